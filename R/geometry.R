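# Planar polygon utilities used by the parcellation, assignment and
# synthetic-data code. Polygons are closed rings stored as two-column
# matrices (x_um, y_um) without a repeated final vertex.

#' Polygon area and centroid (shoelace formulas)
#' @param poly Two-column vertex matrix (um), closed ring without repeated
#'   final vertex.
#' @return Area in um^2, or the centroid as a length-2 vector.
#' @export
polygon_area <- function(poly) {
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

polygon_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}

#' Test points against a polygon
#'
#' @param x,y Numeric point coordinates (um).
#' @param poly Two-column vertex matrix (closed ring, last vertex not
#'   repeated).
#' @param boundary Count boundary points as inside?
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, poly, boundary = TRUE) {
  if (length(x) == 0) return(logical(0))
  res <- pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = boundary)
  as.logical(res)
}

# Proper segment intersection (shared endpoints do not count).
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  eps <- 1e-9
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < -eps) && (d3 * d4 < -eps)
}

polygon_edges <- function(poly) {
  n <- nrow(poly)
  list(a = poly, b = poly[c(2:n, 1), , drop = FALSE])
}

#' Is a polygon simple (no self-intersection)?
#' @param poly Two-column vertex matrix.
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  e <- polygon_edges(poly)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(e$a[i, ], e$b[i, ], e$a[j, ], e$b[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Pairwise interior disjointness: no proper edge crossings and neither
# centroid inside the other. Shared (conforming) edges are allowed.
polygons_interiors_disjoint <- function(pa, pb) {
  ea <- polygon_edges(pa); eb <- polygon_edges(pb)
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      if (segments_cross(ea$a[i, ], ea$b[i, ], eb$a[j, ], eb$b[j, ])) return(FALSE)
    }
  }
  ca <- polygon_centroid(pa); cb <- polygon_centroid(pb)
  if (points_in_polygon(ca[1], ca[2], pb, boundary = FALSE)) return(FALSE)
  if (points_in_polygon(cb[1], cb[2], pa, boundary = FALSE)) return(FALSE)
  TRUE
}

# Rejection-sample n uniform points in a polygon (vectorised over batches).
runif_in_polygon <- function(n, poly, max_tries = 1000L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2,
                            dimnames = list(NULL, c("x", "y"))))
  bb <- polygon_bbox(poly)
  out <- matrix(NA_real_, nrow = 0, ncol = 2)
  tries <- 0L
  while (nrow(out) < n && tries < max_tries) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- points_in_polygon(px, py, poly, boundary = FALSE)
    out <- rbind(out, cbind(px[keep], py[keep]))
    tries <- tries + 1L
  }
  if (nrow(out) < n) {
    stop("failed to sample points inside polygon (degenerate geometry?)")
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Uniform points in a disc intersected with a polygon; falls back to the
# disc centre if the intersection is (numerically) empty.
runif_in_disc_polygon <- function(n, centre, radius, poly, max_tries = 200L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  out <- matrix(NA_real_, nrow = 0, ncol = 2)
  tries <- 0L
  while (nrow(out) < n && tries < max_tries) {
    m <- max(4L * (n - nrow(out)), 16L)
    r <- radius * sqrt(stats::runif(m))
    a <- stats::runif(m, 0, 2 * pi)
    px <- centre[1] + r * cos(a)
    py <- centre[2] + r * sin(a)
    keep <- points_in_polygon(px, py, poly, boundary = FALSE)
    out <- rbind(out, cbind(px[keep], py[keep]))
    tries <- tries + 1L
  }
  if (nrow(out) < n) {
    pad <- matrix(rep(centre, n - nrow(out)), ncol = 2, byrow = TRUE)
    out <- rbind(out, pad)
  }
  out[seq_len(n), , drop = FALSE]
}
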