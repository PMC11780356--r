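# Synthetic tracing-experiment generator. Emulates the statistical structure
# of projection-specific rabies tracing of pulvinar inputs: per-animal
# variable area borders, one injected target HVA per experiment, 9:1
# L6CT:L5CT cell counts, V1-dominant L5 areal weights, configurable
# reciprocal enrichment (L6) / depletion (L5) within a radius of the
# injection site, multinomial brain-wide region counts, pulvinar-dominated
# starter counts, and superior-colliculus cells with target-dependent polar
# concentration. Everything is deterministic given (config seed, animal id,
# target): each experiment gets its own derived RNG stream.

#' Region and lamina vocabularies
#'
#' `BRAINWIDE_REGIONS` is the controlled vocabulary of major brain regions
#' for brain-wide input counts; `STARTER_NUCLEI` the thalamic nuclei used
#' for starter tabulation; `SC_LAYERS` the superior-colliculus laminae from
#' the surface (zo) inward (dw).
#'
#' @format Character vectors.
#' @export
BRAINWIDE_REGIONS <- c("CTX", "TRN", "SC", "PTN", "dLGN", "vLGN", "ZI",
                       "STR", "TH_other", "MB_other", "HB", "HY")

#' @rdname BRAINWIDE_REGIONS
#' @export
STARTER_NUCLEI <- c("pulvinar", "LD", "POm", "dLGN", "CL")

#' @rdname BRAINWIDE_REGIONS
#' @export
SC_LAYERS <- c("zo", "sg", "op", "ig", "iw", "dg", "dw")

# Pooled region rates (fractions of total inputs) used as generative means.
# Non-SC shares sum to 1 - mean(SC share across targets) so that the pooled
# per-region means equal these values exactly in expectation.
#' Default generative rates
#'
#' Generator defaults encoding the study conditions: pooled brain-wide
#' region rates, per-target SC rates, layer-specific areal weights, polar
#' concentration parameters and laminar weights.
#'
#' @param layer Corticothalamic layer for areal weights.
#' @return Named numeric vectors (or lists of parameters).
#' @export
default_brainwide_base <- function() {
  c(CTX = 0.414, TRN = 0.151, PTN = 0.108, dLGN = 0.05, vLGN = 0.02,
    ZI = 0.03, STR = 0.03, TH_other = 0.04, MB_other = 0.02,
    HB = 0.0086, HY = 0.01)
}

# Per-target SC input rates (fractions of total inputs).
#' @rdname default_brainwide_base
#' @export
default_sc_fraction_by_target <- function() {
  c(PM = 0.103, AM = 0.064, RL = 0.069, AL = 0.117, LM = 0.239)
}

#' @rdname default_brainwide_base
#' @export
default_areal_weights <- function(layer = c("L6", "L5")) {
  layer <- match.arg(layer)
  if (layer == "L5") {
    # driver input dominated by V1, substantial retrosplenial contribution
    c(V1 = 0.62, PM = 0.03, AM = 0.03, RL = 0.03, AL = 0.03, LM = 0.03,
      RSP = 0.15, SS = 0.02, PPC = 0.02, AUD = 0.02, TEa = 0.02)
  } else {
    # modulator input distributed across V1 and HVAs
    c(V1 = 0.40, PM = 0.08, AM = 0.08, RL = 0.08, AL = 0.08, LM = 0.08,
      RSP = 0.10, SS = 0.025, PPC = 0.025, AUD = 0.025, TEa = 0.025)
  }
}

#' @rdname default_brainwide_base
#' @export
default_sc_theta_params <- function() {
  # medial (high-theta) concentration for LM- and PM-projecting populations,
  # broader centromedial/centrolateral spread for AM, RL, AL
  list(PM = list(location = 70, scale = 12),
       AM = list(location = 45, scale = 22),
       RL = list(location = 45, scale = 22),
       AL = list(location = 50, scale = 20),
       LM = list(location = 75, scale = 12))
}

#' @rdname default_brainwide_base
#' @export
default_sc_layer_weights <- function() {
  c(zo = 0.03, sg = 0.12, op = 0.25, ig = 0.30, iw = 0.12, dg = 0.12,
    dw = 0.06)
}

check_prob_vector <- function(w, what) {
  if (any(w < 0)) stop(what, " has negative entries")
  if (abs(sum(w) - 1) > 1e-9) stop(what, " does not sum to 1 (sum = ", sum(w), ")")
  invisible(w)
}

#' Configuration for the synthetic tracing-experiment generator
#'
#' Defaults encode the study conditions the analyses assume: five target
#' HVAs with 4-5 animals each, a 9:1 L6CT:L5CT cell ratio, a 400 um
#' reciprocity radius, pooled brain-wide region rates dominated by cortex
#' (41.4%), TRN, SC and pretectum, ~82% of starters in the pulvinar, and
#' target-dependent polar concentration of SC inputs.
#'
#' @param seed Integer master seed.
#' @param n_animals_per_target Animals per target HVA.
#' @param targets Candidate target HVA names.
#' @param n_L6_cells,n_L5_cells Input cells generated per experiment for the
#'   two corticothalamic layers (defaults keep the 9:1 ratio).
#' @param l6_reciprocal_multiplier,l5_reciprocal_multiplier Density
#'   multiplier applied inside the reciprocity radius around the injection
#'   site (>1 plants enrichment, <1 depletion, 1 = no planted effect).
#' @param reciprocity_radius_um Radius (um) of the planted-effect disc.
#' @param areal_weights_L5,areal_weights_L6 Named probability vectors over
#'   areas (or named list with one such vector per target).
#' @param brainwide_base Named non-SC region rates; rescaled per target so
#'   they fill 1 minus the target's SC rate.
#' @param sc_fraction_by_target Named SC input rate per target.
#' @param starter_weights Named probability vector over thalamic nuclei.
#' @param n_starters,n_brainwide,n_sc_cells Count totals per experiment.
#' @param sc_theta_params Named list per target: `location` and `scale`
#'   (degrees) of the truncated-normal polar angle; `scale = Inf` gives a
#'   uniform angle, `scale = 0` a point mass.
#' @param sc_layer_weights Named probability vector over the seven SC
#'   laminae.
#' @param border_jitter_um Maximum vertex displacement (um) of per-animal
#'   area borders from the template map.
#' @param l5_top_um,l5_bottom_um,l6_bottom_um Depth interval (um below pia)
#'   of the L5 marker band and the bottom of L6 used when drawing depths.
#' @param n_landmarks Landmarks generated per adjacent section pair.
#' @param landmark_noise_um Gaussian noise (um, SD) added to landmark
#'   observations in synthetic section stacks.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(seed = 1L,
                         n_animals_per_target = 5L,
                         targets = HVA_NAMES,
                         n_L6_cells = 999L,
                         n_L5_cells = 111L,
                         l6_reciprocal_multiplier = 1,
                         l5_reciprocal_multiplier = 1,
                         reciprocity_radius_um = 400,
                         areal_weights_L5 = default_areal_weights("L5"),
                         areal_weights_L6 = default_areal_weights("L6"),
                         brainwide_base = default_brainwide_base(),
                         sc_fraction_by_target = default_sc_fraction_by_target(),
                         starter_weights = c(pulvinar = 0.82, LD = 0.10,
                                             POm = 0.03, dLGN = 0.03,
                                             CL = 0.02),
                         n_starters = 400L,
                         n_brainwide = 4000L,
                         n_sc_cells = 300L,
                         sc_theta_params = default_sc_theta_params(),
                         sc_layer_weights = default_sc_layer_weights(),
                         border_jitter_um = 50,
                         l5_top_um = 550,
                         l5_bottom_um = 700,
                         l6_bottom_um = 900,
                         n_landmarks = 6L,
                         landmark_noise_um = 0) {
  cfg <- list(seed = as.integer(seed),
              n_animals_per_target = as.integer(n_animals_per_target),
              targets = targets,
              n_L6_cells = as.integer(n_L6_cells),
              n_L5_cells = as.integer(n_L5_cells),
              l6_reciprocal_multiplier = l6_reciprocal_multiplier,
              l5_reciprocal_multiplier = l5_reciprocal_multiplier,
              reciprocity_radius_um = reciprocity_radius_um,
              areal_weights_L5 = areal_weights_L5,
              areal_weights_L6 = areal_weights_L6,
              brainwide_base = brainwide_base,
              sc_fraction_by_target = sc_fraction_by_target,
              starter_weights = starter_weights,
              n_starters = as.integer(n_starters),
              n_brainwide = as.integer(n_brainwide),
              n_sc_cells = as.integer(n_sc_cells),
              sc_theta_params = sc_theta_params,
              sc_layer_weights = sc_layer_weights,
              border_jitter_um = border_jitter_um,
              l5_top_um = l5_top_um,
              l5_bottom_um = l5_bottom_um,
              l6_bottom_um = l6_bottom_um,
              n_landmarks = as.integer(n_landmarks),
              landmark_noise_um = landmark_noise_um)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$reciprocity_radius_um <= 0) stop("reciprocity_radius_um must be > 0")
  if (cfg$l6_reciprocal_multiplier < 0 || cfg$l5_reciprocal_multiplier < 0) {
    stop("reciprocal multipliers must be >= 0")
  }
  if (cfg$border_jitter_um < 0) stop("border_jitter_um must be >= 0")
  if (length(cfg$targets) < 1) stop("at least one target HVA is required")
  for (nm in c("areal_weights_L5", "areal_weights_L6")) {
    w <- cfg[[nm]]
    if (is.list(w)) lapply(names(w), function(t) check_prob_vector(w[[t]], paste(nm, t)))
    else check_prob_vector(w, nm)
  }
  check_prob_vector(cfg$starter_weights, "starter_weights")
  check_prob_vector(cfg$sc_layer_weights, "sc_layer_weights")
  if (any(cfg$brainwide_base < 0)) stop("brainwide_base has negative entries")
  if (any(cfg$sc_fraction_by_target < 0) || any(cfg$sc_fraction_by_target >= 1)) {
    stop("sc_fraction_by_target entries must be in [0, 1)")
  }
  missing_theta <- setdiff(cfg$targets, names(cfg$sc_theta_params))
  if (length(missing_theta)) {
    stop("sc_theta_params missing for target(s): ",
         paste(missing_theta, collapse = ", "))
  }
  if (!(0 < cfg$l5_top_um && cfg$l5_top_um < cfg$l5_bottom_um &&
        cfg$l5_bottom_um < cfg$l6_bottom_um)) {
    stop("layer depth bounds must satisfy 0 < l5_top < l5_bottom < l6_bottom")
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic tracing config (seed", x$seed, ")\n")
  cat("  targets:", paste(x$targets, collapse = ", "),
      "x", x$n_animals_per_target, "animals\n")
  cat("  cells per experiment: L6", x$n_L6_cells, "/ L5", x$n_L5_cells, "\n")
  cat("  reciprocity: x", x$l6_reciprocal_multiplier, "(L6), x",
      x$l5_reciprocal_multiplier, "(L5) within",
      x$reciprocity_radius_um, "um\n")
  invisible(x)
}

#' Per-target brain-wide region weights
#'
#' The target's SC rate is taken from `sc_fraction_by_target`; the non-SC
#' base rates are rescaled to fill the remaining probability mass, so pooled
#' per-region means across targets equal the configured base rates.
#'
#' @param config A `synth_config`.
#' @param target Target HVA name.
#' @return Named probability vector over brain-wide regions.
#' @export
brainwide_weights_for <- function(config, target) {
  sc <- config$sc_fraction_by_target[[target]]
  if (is.null(sc)) stop("no SC fraction configured for target '", target, "'")
  base <- config$brainwide_base
  w <- c(base * (1 - sc) / sum(base), SC = unname(sc))
  w[BRAINWIDE_REGIONS]
}

areal_weights_for <- function(config, layer, target) {
  w <- if (layer == "L5") config$areal_weights_L5 else config$areal_weights_L6
  if (is.list(w)) w <- w[[target]]
  if (is.null(w)) stop("no ", layer, " areal weights for target '", target, "'")
  w
}

#' Generate a per-animal flatmap parcellation
#'
#' Jitters the template map's vertices by at most `border_jitter_um` each.
#' Vertices shared between adjacent areas are jittered jointly, so the
#' conforming-mesh topology (disjoint interiors) is preserved; if jitter
#' still produces an invalid map it is retried with halved jitter a bounded
#' number of times.
#'
#' @param config A `synth_config`.
#' @param animal_id Animal identifier (part of the RNG stream key).
#' @return A `flatmap_parcellation` containing V1, the five target HVAs and
#'   five surrounding non-visual areas; deterministic given (seed, animal).
#' @export
make_flatmap <- function(config, animal_id) {
  template <- template_flatmap_areas()
  jitter <- config$border_jitter_um
  if (jitter == 0) {
    # template mesh is conforming by construction
    return(flatmap_parcellation(animal_id, template, validate = FALSE))
  }
  stream <- derive_seed(config$seed, "flatmap", animal_id)
  for (attempt in 1:6) {
    parc <- with_seed(stream + attempt - 1L, {
      areas <- jitter_template(template, jitter)
      try(flatmap_parcellation(animal_id, areas), silent = TRUE)
    })
    if (!inherits(parc, "try-error")) return(parc)
    jitter <- jitter / 2
  }
  stop("could not generate a non-overlapping parcellation for animal '",
       animal_id, "' even after reducing border jitter")
}

jitter_template <- function(template, jitter) {
  if (jitter == 0) return(template)
  verts <- unique(do.call(rbind, template))
  key <- paste(round(verts[, 1], 6), round(verts[, 2], 6))
  r <- jitter * sqrt(stats::runif(nrow(verts)))
  a <- stats::runif(nrow(verts), 0, 2 * pi)
  dx <- r * cos(a); dy <- r * sin(a)
  names(dx) <- names(dy) <- key
  lapply(template, function(p) {
    k <- paste(round(p[, 1], 6), round(p[, 2], 6))
    cbind(x = p[, 1] + dx[k], y = p[, 2] + dy[k])
  })
}

#' Generate one complete synthetic tracing experiment
#'
#' Draws an injection site uniformly inside the target polygon, places L5
#' and L6 input cells area-wise from the configured areal weights (uniform
#' within each polygon), applies the planted reciprocity effect by
#' multiplying cell intensity inside the reciprocity disc (thinning for
#' multipliers < 1, superposed duplicates for multipliers > 1), and attaches
#' multinomial brain-wide counts, starter counts and an SC cell sample.
#'
#' @param config A `synth_config`.
#' @param target Target HVA (must be in `config$targets`).
#' @param animal_id Animal identifier.
#' @return A `trio_experiment` object.
#' @export
make_experiment <- function(config, target, animal_id) {
  if (!target %in% config$targets) {
    stop("target '", target, "' is not in config$targets")
  }
  parc <- make_flatmap(config, animal_id)
  if (polygon_area(parc$areas[[target]]) <= 0) {
    stop("target polygon '", target, "' is empty")
  }
  stream <- derive_seed(config$seed, "experiment", animal_id, target)
  with_seed(stream, {
    site <- drop(runif_in_polygon(1, parc$areas[[target]]))
    l6 <- place_layer_cells(config, parc, target, "L6", config$n_L6_cells)
    l5 <- place_layer_cells(config, parc, target, "L5", config$n_L5_cells)
    l6 <- apply_reciprocity(l6, site, config$reciprocity_radius_um,
                            config$l6_reciprocal_multiplier, config, parc)
    l5 <- apply_reciprocity(l5, site, config$reciprocity_radius_um,
                            config$l5_reciprocal_multiplier, config, parc)
    cells <- rbind(l6, l5)
    if (nrow(cells)) {
      cells$cell_id <- sprintf("%s_%s_%05d", animal_id, target,
                               seq_len(nrow(cells)))
      cells$animal_id <- animal_id
      cells$target <- target
      cells$channel <- "GFP_input"
      cells <- cells[, c("cell_id", "animal_id", "target", "x_um", "y_um",
                         "section", "depth_um", "layer", "area", "channel")]
    }
    bw <- drop(stats::rmultinom(1, config$n_brainwide,
                                brainwide_weights_for(config, target)))
    names(bw) <- BRAINWIDE_REGIONS
    st <- drop(stats::rmultinom(1, config$n_starters, config$starter_weights))
    names(st) <- names(config$starter_weights)
    sc <- make_sc_sample(config, target, animal_id = animal_id)
    structure(list(animal_id = animal_id,
                   target = target,
                   parcellation = parc,
                   injection_site = site,
                   cells = cells,
                   starters = st,
                   brainwide = bw,
                   sc_cells = sc,
                   config_seed = config$seed),
              class = "trio_experiment")
  })
}

place_layer_cells <- function(config, parc, target, layer, n) {
  w <- areal_weights_for(config, layer, target)
  unknown <- setdiff(names(w), names(parc$areas))
  if (length(unknown)) {
    stop("areal weights name unmapped area(s): ", paste(unknown, collapse = ", "))
  }
  counts <- drop(stats::rmultinom(1, n, w))
  names(counts) <- names(w)
  pieces <- lapply(names(counts)[counts > 0], function(a) {
    xy <- runif_in_polygon(counts[[a]], parc$areas[[a]])
    data.frame(x_um = xy[, 1], y_um = xy[, 2], area = a)
  })
  df <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(x_um = numeric(0), y_um = numeric(0), area = character(0))
  df$layer <- rep(layer, nrow(df))
  df$depth_um <- draw_depth(config, layer, nrow(df))
  df$section <- section_from_depth(df$depth_um)
  df
}

draw_depth <- function(config, layer, n) {
  if (layer == "L5") stats::runif(n, config$l5_top_um, config$l5_bottom_um)
  else stats::runif(n, config$l5_bottom_um, config$l6_bottom_um)
}

# Section 0 is the 250 um surface section; deeper tissue is cut in 50 um
# increments.
section_from_depth <- function(depth_um) {
  ifelse(depth_um < 250, 0L, 1L + as.integer((depth_um - 250) %/% 50))
}

# Intensity multiplication inside the disc around the injection site:
# thinning for m < 1, per-cell superposed duplicates (placed uniformly in
# the disc within the parent cell's area) for m > 1.
apply_reciprocity <- function(df, site, radius, m, config, parc) {
  if (m == 1 || nrow(df) == 0) return(df)
  d <- sqrt((df$x_um - site[1])^2 + (df$y_um - site[2])^2)
  inside <- d <= radius
  if (m < 1) {
    keep <- !inside | (stats::runif(nrow(df)) < m)
    return(df[keep, , drop = FALSE])
  }
  idx <- which(inside)
  if (!length(idx)) return(df)
  n_extra <- floor(m - 1) + stats::rbinom(length(idx), 1, (m - 1) %% 1)
  extras <- lapply(seq_along(idx)[n_extra > 0], function(j) {
    i <- idx[j]
    xy <- runif_in_disc_polygon(n_extra[j], site, radius,
                                parc$areas[[df$area[i]]])
    data.frame(x_um = xy[, 1], y_um = xy[, 2], area = df$area[i])
  })
  if (!length(extras)) return(df)
  extra <- do.call(rbind, extras)
  extra$layer <- df$layer[1]
  extra$depth_um <- draw_depth(config, df$layer[1], nrow(extra))
  extra$section <- section_from_depth(extra$depth_um)
  rbind(df, extra)
}

#' Generate a synthetic superior-colliculus cell sample
#'
#' The SC coronal cross-section is modelled as a quarter annulus so the
#' polar angle and laminar radius are analytically exact: the origin is the
#' intersection of the midline with the ventral SC boundary, the ventral
#' boundary ray is theta = 0 and the midline theta = 90 degrees. Laminae are
#' concentric shells from zo (outermost) to dw (innermost). AP positions are
#' uniform over [-4.80, -2.80] mm from bregma; theta follows the target's
#' truncated-normal parameters.
#'
#' @param config A `synth_config`.
#' @param target Target HVA name.
#' @param animal_id Optional animal id (RNG stream key); `NULL` for a pooled
#'   sample.
#' @param n Number of cells (default `config$n_sc_cells`).
#' @return Data frame with `cell_id`, `target`, `ap_mm`, `x_um`, `y_um`,
#'   `layer` and the generative `theta_true` (degrees).
#' @export
make_sc_sample <- function(config, target, animal_id = NULL,
                           n = config$n_sc_cells) {
  pars <- config$sc_theta_params[[target]]
  if (is.null(pars)) stop("sc_theta_params missing for target '", target, "'")
  stream <- derive_seed(config$seed, "sc", target,
                        if (is.null(animal_id)) "pooled" else animal_id)
  with_seed(stream, {
    theta <- draw_trunc_theta(n, pars$location, pars$scale)
    geom <- sc_bin_geometry()
    layer <- sample(SC_LAYERS, n, replace = TRUE,
                    prob = config$sc_layer_weights)
    r <- shell_radius(layer, geom)
    data.frame(cell_id = sprintf("sc_%s_%04d", target, seq_len(n)),
               target = target,
               ap_mm = stats::runif(n, -4.80, -2.80),
               x_um = geom$origin[1] + r * cos(theta * pi / 180),
               y_um = geom$origin[2] + r * sin(theta * pi / 180),
               layer = layer,
               theta_true = theta)
  })
}

draw_trunc_theta <- function(n, location, scale) {
  if (!is.finite(scale)) return(stats::runif(n, 0, 90))
  if (scale <= 1e-12) return(rep(location, n))
  lo <- stats::pnorm((0 - location) / scale)
  hi <- stats::pnorm((90 - location) / scale)
  location + scale * stats::qnorm(stats::runif(n, lo, hi))
}

#' Analytic quarter-annulus geometry of an SC coronal bin
#'
#' @return List with `origin` (midline x ventral boundary intersection, um),
#'   `r_inner`, `r_outer` (um) and per-lamina shell bounds from the outer
#'   surface (zo) inward (dw).
#' @export
sc_bin_geometry <- function() {
  r_in <- 400; r_out <- 1400
  frac <- c(zo = 0.05, sg = 0.15, op = 0.15, ig = 0.25, iw = 0.12,
            dg = 0.18, dw = 0.10)
  outer <- r_out - c(0, cumsum(frac)[-length(frac)]) * (r_out - r_in)
  inner <- r_out - cumsum(frac) * (r_out - r_in)
  list(origin = c(0, 0), r_inner = r_in, r_outer = r_out,
       shells = data.frame(layer = names(frac), r_outer = unname(outer),
                           r_inner = unname(inner)))
}

shell_radius <- function(layer, geom) {
  sh <- geom$shells
  i <- match(layer, sh$layer)
  stats::runif(length(layer), sh$r_inner[i], sh$r_outer[i])
}

#' Generate a synthetic serial-section stack with known alignments
#'
#' Each adjacent section pair gets a small ground-truth affine perturbation
#' (rotation, translation, isotropic scale) and `config$n_landmarks`
#' landmark pairs observed in both frames, optionally with Gaussian noise.
#' The true transforms are stored for recovery tests.
#'
#' @param config A `synth_config`.
#' @param n_sections Number of sections (>= 2); section 0 is the surface.
#' @return A `section_stack`: section indices, per-pair landmark tables
#'   (deeper-frame source, shallower-frame target) and the true
#'   deeper-to-shallower transforms.
#' @export
make_section_stack <- function(config, n_sections) {
  if (n_sections < 2) stop("n_sections must be >= 2")
  if (config$n_landmarks < 3) {
    stop("at least 3 landmarks per section pair are required")
  }
  stream <- derive_seed(config$seed, "stack", n_sections)
  with_seed(stream, {
    truths <- vector("list", n_sections - 1)
    pairs <- vector("list", n_sections - 1)
    for (k in seq_len(n_sections - 1)) {
      ang <- stats::runif(1, -2, 2) * pi / 180
      sc <- stats::runif(1, 0.98, 1.02)
      tr <- stats::runif(2, -20, 20)
      A <- affine2d(rbind(c(sc * cos(ang), -sc * sin(ang), tr[1]),
                          c(sc * sin(ang),  sc * cos(ang), tr[2])))
      src <- cbind(stats::runif(config$n_landmarks, 0, 3000),
                   stats::runif(config$n_landmarks, 0, 3000))
      tgt <- apply_affine(A, src)
      if (config$landmark_noise_um > 0) {
        tgt <- tgt + matrix(stats::rnorm(length(tgt), 0,
                                         config$landmark_noise_um),
                            ncol = 2)
      }
      truths[[k]] <- A
      pairs[[k]] <- data.frame(section_a = k, xa = src[, 1], ya = src[, 2],
                               section_b = k - 1, xb = tgt[, 1],
                               yb = tgt[, 2], kind = "radial_vessel")
    }
    structure(list(sections = 0:(n_sections - 1), landmarks = pairs,
                   truth = truths, seed = config$seed),
              class = "section_stack")
  })
}

#' @export
print.trio_experiment <- function(x, ...) {
  cat("Tracing experiment", x$animal_id, "-> target", x$target, "\n")
  cat("  input cells:", nrow(x$cells),
      sprintf("(L6 %d / L5 %d)", sum(x$cells$layer == "L6"),
              sum(x$cells$layer == "L5")), "\n")
  cat("  starters:", sum(x$starters), "| brain-wide inputs:",
      sum(x$brainwide), "| SC cells:", nrow(x$sc_cells), "\n")
  invisible(x)
}

#' Generate the full set of experiments for a configuration
#'
#' @param config A `synth_config`.
#' @return List of `trio_experiment`, one per (target, animal) combination,
#'   with animal ids `<target><i>`.
#' @export
make_experiments <- function(config) {
  out <- list()
  for (t in config$targets) {
    for (i in seq_len(config$n_animals_per_target)) {
      id <- paste0(t, i)
      out[[id]] <- make_experiment(config, t, id)
    }
  }
  out
}
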