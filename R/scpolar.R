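# Superior-colliculus input analysis: anterior-posterior binning, polar
# angle theta per cell (ventral SC boundary = 0 deg, midline = 90 deg),
# per-lamina input fractions, and boundary-corrected theta probability
# densities pooled across animals per target.

SC_AP_CENTERS <- c(-3.05, -3.55, -4.05, -4.55)

#' Bin SC cells along the anterior-posterior axis
#'
#' Four 500 um bins spanning -2.80 to -4.80 mm from bregma with centres at
#' -3.05, -3.55, -4.05 and -4.55 mm. Bins are half-open on the anterior
#' side ([-2.80, -3.30), ...); the most posterior bin includes its
#' posterior edge. Out-of-range cells get `NA` and are flagged.
#'
#' @param ap_mm Anterior-posterior positions (mm from bregma, negative).
#' @return Integer bin index 1-4 (`NA` = out of range), with attribute
#'   `centers_mm`.
#' @export
ap_bin <- function(ap_mm) {
  stopifnot(all(is.finite(ap_mm)))
  edges <- c(2.80, 3.30, 3.80, 4.30, 4.80)
  b <- findInterval(-ap_mm, edges, rightmost.closed = TRUE)
  b[b < 1 | b > 4] <- NA_integer_
  n_out <- sum(is.na(b))
  if (n_out > 0) {
    attr(b, "n_out_of_range") <- n_out
  }
  attr(b, "centers_mm") <- SC_AP_CENTERS
  b
}

#' Polar angle of SC cells
#'
#' Theta is the angle between the ray from the bin origin (midline crossed
#' with the ventral SC boundary) to the cell and the ventral-boundary ray,
#' in degrees, clipped to [0, 90]. Cells at the origin have an undefined
#' angle (`NA`).
#'
#' @param cells Data frame with `x_um`, `y_um` (coronal plane).
#' @param geometry Bin geometry as from [sc_bin_geometry()] (`origin`, with
#'   the ventral-boundary ray along +x and the midline along +y).
#' @return Numeric theta in degrees.
#' @export
compute_theta <- function(cells, geometry = sc_bin_geometry()) {
  dx <- cells$x_um - geometry$origin[1]
  dy <- cells$y_um - geometry$origin[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) * 180 / pi
  theta <- pmin(pmax(theta, 0), 90)
  theta[r < 1e-9] <- NA_real_
  theta
}

#' Boundary-corrected kernel density of theta on [0, 90] degrees
#'
#' Gaussian kernel estimate with reflection at both boundaries (the sample
#' is mirrored about 0 and 90, estimated, and folded back), so no density
#' mass leaks outside the support.
#'
#' @param thetas Angles in degrees, n >= 2.
#' @param n_grid Minimum number of evaluation points (grown automatically
#'   so the grid resolves the bandwidth).
#' @param bw Kernel bandwidth (degrees); default Silverman's rule of thumb,
#'   capped at 30 degrees.
#' @return Data frame `grid` (deg), `density` (1/deg); integrates to 1
#'   within 0.01.
#' @export
theta_pdf <- function(thetas, n_grid = 512, bw = NULL) {
  thetas <- thetas[!is.na(thetas)]
  if (length(thetas) < 2) {
    stop("at least 2 theta values are required for a density estimate")
  }
  if (any(thetas < 0 | thetas > 90)) stop("theta values must lie in [0, 90]")
  if (is.null(bw)) bw <- min(safe_bw(thetas), 30)
  aug <- c(thetas, -thetas, 180 - thetas)
  n_grid <- resolve_grid(n_grid, 90, bw)
  d <- stats::density(aug, bw = bw, from = 0, to = 90, n = n_grid)
  data.frame(grid = d$x, density = 3 * d$y)
}

#' Per-lamina SC input fractions of total inputs
#'
#' Distributes the experiment's total SC input fraction across the seven
#' laminae according to the SC cell sample, so the per-layer fractions sum
#' to the experiment's SC fraction of total inputs.
#'
#' @param experiment A `trio_experiment` (uses `$sc_cells` and
#'   `$brainwide`).
#' @return Named numeric vector over `zo, sg, op, ig, iw, dg, dw`.
#' @export
sc_layer_fractions <- function(experiment) {
  total <- sum(experiment$brainwide)
  if (total == 0) stop("experiment has no recorded inputs")
  sc_frac <- experiment$brainwide[["SC"]] / total
  out <- stats::setNames(rep(0, length(SC_LAYERS)), SC_LAYERS)
  n_sc <- nrow(experiment$sc_cells)
  if (n_sc == 0) return(out)
  tab <- table(factor(experiment$sc_cells$layer, levels = SC_LAYERS))
  out[] <- sc_frac * as.numeric(tab) / n_sc
  out
}

#' Pool SC cells across animals per target
#'
#' Simple concatenation without per-animal weighting, so animals with
#' inefficient SC labelling do not skew the pooled distribution.
#'
#' @param experiments List of `trio_experiment`.
#' @param superficial_layers Laminae classed as superficial (the rest are
#'   deep).
#' @return Data frame of pooled SC cells with `target`, `ap_bin`,
#'   `theta_deg` and `depth_class` columns.
#' @export
pool_by_target <- function(experiments,
                           superficial_layers = c("zo", "sg", "op")) {
  pieces <- lapply(experiments, function(e) {
    sc <- e$sc_cells
    if (is.null(sc) || nrow(sc) == 0) return(NULL)
    sc$animal_id <- e$animal_id
    sc
  })
  pooled <- do.call(rbind, pieces)
  if (is.null(pooled) || nrow(pooled) == 0) {
    stop("no SC cells available to pool")
  }
  pooled$ap_bin <- as.integer(ap_bin(pooled$ap_mm))
  pooled$theta_deg <- compute_theta(pooled)
  pooled$depth_class <- ifelse(pooled$layer %in% superficial_layers,
                               "superficial", "deep")
  rownames(pooled) <- NULL
  pooled
}
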