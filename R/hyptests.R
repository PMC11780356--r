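# Classical tests used alongside the permutation framework:
# Kruskal-Wallis with Dunn-Sidak post hoc, Monte-Carlo Fisher exact with a
# precision-driven shuffle count, Pearson chi-squared independence, and the
# standard error of a proportion.

#' Kruskal-Wallis rank test across groups
#'
#' @param groups List of numeric vectors (>= 2 nonempty groups).
#' @return List with `H` (tie-corrected statistic), `df` and `p` (from the
#'   chi-squared distribution with k - 1 df). All-identical values yield a
#'   degenerate flag with `H = NA`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (any(vapply(groups, length, 1L) == 0)) stop("groups must be nonempty")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = NA_real_, df = length(groups) - 1L, p = NA_real_,
                degenerate = TRUE))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, degenerate = FALSE)
}

#' Sidak adjustment of a p-value for m comparisons
#' @param p Raw p-value(s).
#' @param m Number of comparisons in the family.
#' @return Adjusted p-value(s) `1 - (1 - p)^m`.
#' @export
sidak_adjust <- function(p, m) {
  1 - (1 - p)^m
}

#' Dunn's post hoc pairwise tests with Sidak adjustment
#'
#' Pairwise z-tests on pooled ranks with tie correction, applied post hoc
#' after a significant Kruskal-Wallis test (gatekeeping). Adjusted p-values
#' are `1 - (1 - p)^m` over the m pairwise comparisons.
#'
#' @param groups Named list of numeric vectors.
#' @param gate_alpha Kruskal-Wallis significance threshold gating the post
#'   hoc (set to 1 to disable gatekeeping).
#' @return List with `kw` (the omnibus result) and `pairs`, a data frame of
#'   pairwise `z`, `p_raw`, `p_sidak` (empty when gated out).
#' @export
dunn_sidak <- function(groups, gate_alpha = 0.05) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal_wallis(groups)
  empty <- data.frame(group1 = character(0), group2 = character(0),
                      z = numeric(0), p_raw = numeric(0),
                      p_sidak = numeric(0))
  if (isTRUE(kw$degenerate) || kw$p > gate_alpha) {
    return(list(kw = kw, pairs = empty, gated = TRUE))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  cmb <- utils::combn(names(groups), 2)
  m <- ncol(cmb)
  z <- p_raw <- numeric(m)
  for (k in seq_len(m)) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt(v0 * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  list(kw = kw,
       pairs = data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = z,
                          p_raw = p_raw,
                          p_sidak = pmin(1, sidak_adjust(p_raw, m))),
       gated = FALSE)
}

# log conditional probability of a contingency table given its margins
# (multivariate hypergeometric).
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Fisher's exact test by Monte-Carlo simulation
#'
#' Samples tables with the observed margins fixed (Patefield algorithm via
#' `r2dtable`) and estimates the p-value as the proportion of tables whose
#' conditional probability is at most the observed table's (with a small
#' tolerance for floating-point ties), using the add-one correction
#' `(1 + k) / (1 + N)`. The binomial Monte-Carlo standard error is
#' reported.
#'
#' @param table Nonnegative integer matrix (rows = input areas, columns =
#'   target HVAs) with positive margins and at least two rows and columns.
#' @param n_shuffles Number of simulated tables.
#' @param seed RNG seed.
#' @return List with `p`, `mc_se`, `n_shuffles` and `seed`.
#' @export
fisher_mc <- function(table, n_shuffles = 10000, seed = 1L) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain nonnegative integers")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("table must have at least 2 rows and 2 columns")
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("table has a zero row or column margin")
  }
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  lp_obs <- log_table_prob(tab)
  tol <- 1e-7
  k <- with_seed(seed, {
    hits <- 0L
    left <- n_shuffles
    while (left > 0) {
      m <- min(left, 50000L)
      sims <- stats::r2dtable(m, rs, cs)
      lp <- vapply(sims, log_table_prob, numeric(1))
      hits <- hits + sum(lp <= lp_obs + tol)
      left <- left - m
    }
    hits
  })
  p <- (1 + k) / (1 + n_shuffles)
  list(p = p, mc_se = sqrt(p * (1 - p) / n_shuffles),
       n_shuffles = n_shuffles, seed = seed)
}

#' Monte-Carlo shuffle count for a target p-value precision
#'
#' Worst-case (p = 0.5) binomial sizing: `N = ceiling(z^2 / (4 h^2))` with
#' `z` the two-sided normal quantile at the requested confidence and `h`
#' the desired half-width of the p-value confidence interval. At h = 1e-4
#' and 95% confidence this gives 9.604e7 shuffles.
#'
#' @param half_width Desired half-width of the p-value interval (0 < h < 1).
#' @param confidence Confidence level (0 < c < 1).
#' @return Integer-valued number of shuffles.
#' @export
mc_shuffles_needed <- function(half_width, confidence = 0.95) {
  if (half_width <= 0 || half_width >= 1) stop("half_width must be in (0, 1)")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  ceiling(z^2 * 0.25 / half_width^2)
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction; df = (r - 1)(c - 1).
#'
#' @param table Nonnegative contingency matrix with positive margins.
#' @return List with `chi2`, `df` and `p`. Errors if any expected cell is
#'   zero, naming the cell.
#' @export
chi2_independence <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("table must have at least 2 rows and 2 columns")
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("table has a zero row or column margin")
  }
  expected <- outer(rs, cs) / sum(tab)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    stop("expected count is zero in cell (", bad[1], ", ", bad[2], ")")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Standard error of a proportion
#' @param p_hat Estimated proportion in [0, 1].
#' @param n Sample size (>= 1).
#' @return `sqrt(p_hat (1 - p_hat) / n)`.
#' @export
se_proportion <- function(p_hat, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(p_hat < 0 | p_hat > 1)) stop("p_hat must lie in [0, 1]")
  sqrt(p_hat * (1 - p_hat) / n)
}
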