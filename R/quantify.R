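# Descriptive quantities: input fractions of total inputs, HVA fractions
# normalised to total visual cortical input, hexagonal density binning,
# distance-to-target samples and kernel densities, pooled summaries, and
# column-normalised relative-strength matrices.

#' Input fractions of total inputs per region
#'
#' @param counts Named nonnegative vector of per-region input counts.
#' @return Named fractions summing to 1.
#' @export
input_fractions <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("no inputs recorded (empty experiment)")
  counts / total
}

#' Per-HVA fractions of total visual cortical input
#'
#' Normalises area counts for one corticothalamic layer to the total over
#' visual areas only, so animals with unusually low cortical labelling do
#' not skew areal comparisons. Adding non-visual counts leaves the result
#' unchanged.
#'
#' @param area_counts Named vector of per-area cell counts for one layer.
#' @param visual_areas Character vector of visual area names.
#' @return Named fractions over `visual_areas` summing to 1, or `NA`
#'   fractions with attribute `undefined = TRUE` when the layer has no
#'   visual input (excluded from group medians downstream).
#' @export
visual_normalized_fractions <- function(area_counts,
                                        visual_areas = VISUAL_AREAS) {
  v <- area_counts[intersect(names(area_counts), visual_areas)]
  full <- stats::setNames(rep(0, length(visual_areas)), visual_areas)
  full[names(v)] <- v
  total <- sum(full)
  if (total == 0) {
    out <- stats::setNames(rep(NA_real_, length(visual_areas)), visual_areas)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  full / total
}

#' Bin points on a hexagonal grid
#'
#' Pointy-top hexagons; `width` is the flat-to-flat (horizontal) distance,
#' and the grid is anchored at `origin`. Bin membership is deterministic
#' and counts are conserved.
#'
#' @param x,y Point coordinates (um).
#' @param width Hexagon width, um (default 180.6).
#' @param origin Grid anchor (um).
#' @return A `hexgrid` data frame: axial indices `q`, `r`, bin centres
#'   `cx`, `cy` (um, absolute) and `count`.
#' @export
hexbin_density <- function(x, y, width = 180.6, origin = c(0, 0)) {
  if (width <= 0) stop("hexagon width must be > 0")
  stopifnot(length(x) == length(y))
  if (length(x) == 0) {
    out <- data.frame(q = integer(0), r = integer(0), cx = numeric(0),
                      cy = numeric(0), count = integer(0))
    class(out) <- c("hexgrid", class(out))
    attr(out, "width") <- width
    return(out)
  }
  size <- width / sqrt(3)            # circumradius
  px <- x - origin[1]; py <- y - origin[2]
  qf <- (sqrt(3) / 3 * px - py / 3) / size
  rf <- (2 / 3 * py) / size
  ax <- hex_round(qf, rf)
  key <- paste(ax$q, ax$r)
  tab <- table(key)
  uq <- ax$q[!duplicated(key)]; ur <- ax$r[!duplicated(key)]
  names(uq) <- names(ur) <- key[!duplicated(key)]
  kk <- names(tab)
  out <- data.frame(q = as.integer(uq[kk]), r = as.integer(ur[kk]),
                    count = as.integer(tab))
  out$cx <- size * sqrt(3) * (out$q + out$r / 2) + origin[1]
  out$cy <- size * 1.5 * out$r + origin[2]
  out <- out[order(out$q, out$r), c("q", "r", "cx", "cy", "count")]
  rownames(out) <- NULL
  class(out) <- c("hexgrid", class(out))
  attr(out, "width") <- width
  out
}

# Cube-coordinate rounding for axial hex indices.
hex_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

#' Euclidean distances from cells to a reference point
#'
#' @param cells Data frame with `x_um`, `y_um` (surface frame).
#' @param reference Length-2 numeric reference point (um), typically the
#'   injection site (or the target polygon centroid when no site is
#'   recorded).
#' @return Numeric vector of distances (um).
#' @export
distances_to_target <- function(cells, reference) {
  if (!all(is.finite(reference))) stop("reference point must be finite")
  sqrt((cells$x_um - reference[1])^2 + (cells$y_um - reference[2])^2)
}

#' Proportion of cells within a radius of the reference point
#'
#' The disc is closed: a distance exactly equal to the radius counts as
#' within.
#'
#' @param distances Numeric distances (um).
#' @param radius_um Radius (um).
#' @return List with `proportion` and `n`; proportion is `NA` with an
#'   `undefined` flag for an empty sample.
#' @export
proportion_within_radius <- function(distances, radius_um = 400) {
  n <- length(distances)
  if (n == 0) {
    return(list(proportion = NA_real_, n = 0L, undefined = TRUE))
  }
  list(proportion = mean(distances <= radius_um), n = n, undefined = FALSE)
}

#' Gaussian kernel density of a distance sample
#'
#' Silverman's rule-of-thumb bandwidth with reflection at zero, so no
#' density mass is placed at negative distances.
#'
#' @param distances Nonnegative distances (um), n >= 2.
#' @param n_grid Minimum number of evaluation points (grown automatically
#'   so the grid resolves the bandwidth).
#' @param bw Kernel bandwidth (um); default Silverman's rule of thumb.
#' @return Data frame `grid` (um), `density` (1/um); integrates to 1 within
#'   0.01 on the grid.
#' @export
distance_density <- function(distances, n_grid = 512, bw = NULL) {
  if (length(distances) < 2) {
    stop("at least 2 distances are required for a density estimate")
  }
  if (is.null(bw)) bw <- safe_bw(distances)
  aug <- c(distances, -distances)
  hi <- max(distances) + 4 * bw
  n_grid <- resolve_grid(n_grid, hi, bw)
  d <- stats::density(aug, bw = bw, from = 0, to = hi, n = n_grid)
  data.frame(grid = d$x, density = 2 * d$y)
}

# enough grid points that the spacing is well below the bandwidth
resolve_grid <- function(n_grid, span, bw) {
  min(max(n_grid, ceiling(span / (bw / 4))), 2^15)
}

safe_bw <- function(x) {
  bw <- tryCatch(stats::bw.nrd0(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) {
    spread <- max(stats::sd(x), 1e-6)
    bw <- max(spread / 10, max(abs(x), 1) * 1e-4)
  }
  bw
}

#' Pooled mean and standard error of the mean
#'
#' @param values Per-experiment values, n >= 2 for a defined SEM.
#' @return List with `mean`, `sem` and `n`. SEM uses the sample SD (n - 1
#'   denominator) divided by sqrt(n); for n < 2 the SEM is `NA` with an
#'   `undefined_sem` flag.
#' @export
pooled_mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values supplied")
  if (n < 2) {
    return(list(mean = mean(values), sem = NA_real_, n = n,
                undefined_sem = TRUE))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n,
       undefined_sem = FALSE)
}

#' Median and (unscaled) median absolute deviation
#'
#' @param values Numeric vector, n >= 1. `NA` values are dropped.
#' @return List with `median` and `mad` where
#'   `mad = median(|x - median(x)|)` without a consistency constant.
#' @export
median_mad <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values supplied")
  m <- stats::median(values)
  list(median = m, mad = stats::median(abs(values - m)))
}

#' Column-normalised relative-strength matrix
#'
#' Divides each column (projection target) of a median-input matrix by its
#' maximum, visualising each input relative to the strongest input for that
#' target. All-zero columns are left as zeros and flagged.
#'
#' @param m Numeric matrix (rows = input areas, columns = targets).
#' @return Matrix with entries in `[0, 1]`; attribute `zero_columns` names
#'   any all-zero columns.
#' @export
relative_strength_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("input matrix must be nonnegative")
  mx <- apply(m, 2, max, na.rm = TRUE)
  zero <- which(mx <= 0)
  mx[zero] <- 1
  out <- sweep(m, 2, mx, "/")
  attr(out, "zero_columns") <- colnames(m)[zero]
  out
}
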