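# Shuffled-target permutation framework. The null reassigns each
# experiment's target uniformly at random among the candidate HVAs (the
# original target included, independently across experiments), moves the
# reference point to the shuffled target's centroid in that animal's own
# map, keeps cell positions fixed, and recomputes the statistic. One-tailed
# p-values test reciprocity (upper tail, L6CT) and antireciprocity (lower
# tail, L5CT); families of tests are adjusted with Benjamini-Hochberg.

#' Shuffled-target null distribution of a statistic
#'
#' The per-experiment statistic is evaluated once for every (experiment,
#' candidate target) pair — the candidate's centroid in that animal's map is
#' the reference point — and shuffles then draw candidate indices, so even
#' large shuffle counts are cheap. In exhaustive mode all candidate
#' combinations are enumerated instead of sampled.
#'
#' @param experiments List of `trio_experiment`.
#' @param statistic_fn Function `(experiment, target, reference)` returning
#'   a scalar per-experiment statistic.
#' @param n_shuffles Number of shuffles (ignored in exhaustive mode).
#' @param seed Integer seed for the shuffle draws.
#' @param candidates Candidate target names; default the five HVAs.
#' @param exhaustive Enumerate all candidate combinations?
#' @param aggregate Function collapsing per-experiment values into the
#'   group statistic (default `mean`).
#' @return A `shuffle_null` object: `values` (null sample), the
#'   per-(experiment, candidate) statistic matrix, candidates and seed.
#' @export
shuffle_null <- function(experiments, statistic_fn, n_shuffles = 10000,
                         seed = 1L, candidates = HVA_NAMES,
                         exhaustive = FALSE, aggregate = mean) {
  if (!length(experiments)) stop("no experiments supplied")
  if (!exhaustive && n_shuffles < 1) stop("n_shuffles must be >= 1")
  V <- candidate_statistics(experiments, statistic_fn, candidates)
  n_exp <- nrow(V); n_c <- ncol(V)
  if (exhaustive) {
    if (n_c^n_exp > 1e6) stop("exhaustive enumeration too large (",
                              n_c^n_exp, " combinations)")
    grid <- as.matrix(expand.grid(rep(list(seq_len(n_c)), n_exp)))
    values <- apply(grid, 1, function(ix) {
      aggregate(V[cbind(seq_len(n_exp), ix)])
    })
  } else {
    values <- with_seed(seed, {
      ix <- matrix(sample.int(n_c, n_shuffles * n_exp, replace = TRUE),
                   nrow = n_shuffles)
      apply(ix, 1, function(row) aggregate(V[cbind(seq_len(n_exp), row)]))
    })
  }
  structure(list(values = as.numeric(values), per_candidate = V,
                 candidates = candidates, seed = seed,
                 exhaustive = exhaustive),
            class = "shuffle_null")
}

candidate_statistics <- function(experiments, statistic_fn, candidates) {
  V <- matrix(NA_real_, length(experiments), length(candidates),
              dimnames = list(vapply(experiments, `[[`, "", "animal_id"),
                              candidates))
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    missing <- setdiff(candidates, names(e$parcellation$areas))
    if (length(missing)) {
      stop("animal '", e$animal_id, "' is missing candidate area(s): ",
           paste(missing, collapse = ", "))
    }
    for (j in seq_along(candidates)) {
      ref <- area_centroid(e$parcellation, candidates[j])
      V[i, j] <- statistic_fn(e, candidates[j], ref)
    }
  }
  V
}

#' Permutation p-value from a null sample
#'
#' Sampled nulls use the add-one correction `p = (1 + k) / (N + 1)` (k =
#' shuffles at least as extreme), whose floor `1/(N + 1)` reproduces the
#' `< 1.0e-4` reporting convention at N = 10,000. Exhaustive nulls (the
#' full enumeration, which contains the observed configuration) use the
#' plain proportion.
#'
#' @param observed Observed statistic.
#' @param null_sample Numeric null sample (or a `shuffle_null`).
#' @param tail `"upper"`, `"lower"` or `"two_sided"`.
#' @param exhaustive Is the null the complete enumeration?
#' @return Raw p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null_sample,
                               tail = c("upper", "lower", "two_sided"),
                               exhaustive = FALSE) {
  tail <- match.arg(tail)
  if (inherits(null_sample, "shuffle_null")) {
    exhaustive <- null_sample$exhaustive
    null_sample <- null_sample$values
  }
  if (!length(null_sample)) stop("empty null sample")
  N <- length(null_sample)
  k_up <- sum(null_sample >= observed)
  k_lo <- sum(null_sample <= observed)
  prop <- function(k) if (exhaustive) k / N else (1 + k) / (N + 1)
  switch(tail,
         upper = prop(k_up),
         lower = prop(k_lo),
         two_sided = min(1, 2 * min(prop(k_up), prop(k_lo))))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values Raw p-values in (0, 1].
#' @return Adjusted p-values (step-up procedure), original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Format a permutation p-value with its resolution floor
#'
#' P-values at the sampling floor `1/(N + 1)` are reported as an inequality
#' (e.g. `p < 1.0e-04` for N = 10,000) rather than as zero.
#'
#' @param p Raw p-value.
#' @param n_shuffles Number of shuffles behind `p`.
#' @return Character scalar.
#' @export
format_pvalue <- function(p, n_shuffles) {
  floor_p <- 1 / (n_shuffles + 1)
  if (p <= floor_p + 1e-15) {
    sprintf("p < %.1e", signif(floor_p, 2))
  } else {
    sprintf("p = %.4g", p)
  }
}

#' Shuffled-target test of reciprocity / antireciprocity near the target
#'
#' Observed statistic: mean (across experiments) proportion of layer-L
#' cells within `radius_um` of the reference point — the injection site by
#' default, or the target centroid (the same rule the shuffled null uses,
#' making observed and null exactly exchangeable under no planted effect).
#' Upper tail tests L6CT reciprocal enrichment; lower tail tests L5CT
#' antireciprocity.
#'
#' @param experiments List of `trio_experiment` (typically one target
#'   group).
#' @param layer `"L6"` or `"L5"`.
#' @param tail Test tail.
#' @param radius_um Disc radius (um, default 400).
#' @param n_shuffles Shuffles (default 10,000).
#' @param seed Shuffle seed.
#' @param observed_ref `"site"` (injection site) or `"centroid"`.
#' @param candidates Candidate targets for the shuffle space.
#' @return A `perm_test` result.
#' @export
reciprocity_test <- function(experiments, layer = c("L6", "L5"),
                             tail = if (layer == "L6") "upper" else "lower",
                             radius_um = 400, n_shuffles = 10000, seed = 1L,
                             observed_ref = c("site", "centroid"),
                             candidates = HVA_NAMES) {
  layer <- match.arg(layer)
  observed_ref <- match.arg(observed_ref)
  stat_fn <- function(e, target, ref) {
    cells <- e$cells[e$cells$layer == layer, , drop = FALSE]
    proportion_within_radius(distances_to_target(cells, ref),
                             radius_um)$proportion
  }
  null <- shuffle_null(experiments, stat_fn, n_shuffles = n_shuffles,
                       seed = seed, candidates = candidates)
  obs <- mean(vapply(experiments, function(e) {
    ref <- if (observed_ref == "site") e$injection_site
           else area_centroid(e$parcellation, e$target)
    stat_fn(e, e$target, ref)
  }, numeric(1)))
  perm_test_result(statistic = sprintf("mean within-%g um proportion (%s)",
                                       radius_um, layer),
                   observed = obs, null = null, tail = tail, seed = seed)
}

#' Shuffled-target test on reciprocal-area input fractions
#'
#' Area-count variant of the shuffle: the per-experiment statistic is the
#' fraction of layer-L visual cortical cells assigned to the (shuffled)
#' target area itself.
#'
#' @inheritParams reciprocity_test
#' @return A `perm_test` result.
#' @export
reciprocal_fraction_test <- function(experiments, layer = c("L6", "L5"),
                                     tail = if (layer == "L6") "upper" else "lower",
                                     n_shuffles = 10000, seed = 1L,
                                     candidates = HVA_NAMES) {
  layer <- match.arg(layer)
  stat_fn <- function(e, target, ref) {
    cells <- e$cells[e$cells$layer == layer &
                       e$cells$area %in% VISUAL_AREAS, , drop = FALSE]
    if (nrow(cells) == 0) return(NA_real_)
    mean(cells$area == target)
  }
  null <- shuffle_null(experiments, stat_fn, n_shuffles = n_shuffles,
                       seed = seed, candidates = candidates)
  obs <- mean(vapply(experiments, function(e) {
    stat_fn(e, e$target, NULL)
  }, numeric(1)), na.rm = TRUE)
  perm_test_result(statistic = sprintf("reciprocal visual fraction (%s)", layer),
                   observed = obs, null = null, tail = tail, seed = seed)
}

perm_test_result <- function(statistic, observed, null, tail, seed) {
  p <- permutation_pvalue(observed, null, tail = tail)
  structure(list(statistic = statistic,
                 observed = observed,
                 null = null$values,
                 n_shuffles = length(null$values),
                 tail = tail,
                 p_raw = p,
                 p_adjusted = NA_real_,
                 adjustment = "none",
                 seed = seed),
            class = "perm_test")
}

#' Adjust a family of permutation tests for false discovery rate
#'
#' @param tests List of `perm_test` results (e.g. one per target HVA).
#' @return The list with `p_adjusted` filled in (Benjamini-Hochberg).
#' @export
adjust_tests <- function(tests) {
  p <- vapply(tests, `[[`, numeric(1), "p_raw")
  padj <- bh_adjust(p)
  for (i in seq_along(tests)) {
    tests[[i]]$p_adjusted <- padj[i]
    tests[[i]]$adjustment <- "BH"
  }
  tests
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Shuffled-target permutation test\n")
  cat("  statistic:", x$statistic, "\n")
  cat("  observed:", format(x$observed, digits = 4),
      "| null mean:", format(mean(x$null), digits = 4),
      "(", x$n_shuffles, "shuffles )\n")
  cat("  tail:", x$tail, "|", format_pvalue(x$p_raw, x$n_shuffles))
  if (!is.na(x$p_adjusted)) {
    cat(" | adjusted (", x$adjustment, "): ",
        format(x$p_adjusted, digits = 4), sep = "")
  }
  cat("\n")
  invisible(x)
}
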