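# Landmark-based affine registration of serial tangential sections and
# warping of the in-vivo area map into tissue coordinates. Sections are
# virtually "flattened" by composing least-squares affine fits between
# adjacent sections, deep to superficial, so deep-layer cells line up with
# the surface-frame area borders.

#' Construct a 2D affine transform
#'
#' @param matrix 2x3 numeric matrix: linear part (columns 1-2) and
#'   translation (column 3), in um.
#' @return An `affine2d` object.
#' @export
affine2d <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(2, 3))) stop("affine matrix must be 2x3")
  if (!all(is.finite(m))) stop("affine matrix has non-finite entries")
  if (abs(det(m[, 1:2])) <= 1e-12) {
    stop("linear part is singular (|det| <= 1e-12)")
  }
  structure(list(matrix = m), class = "affine2d")
}

#' Identity affine transform
#' @return An `affine2d`.
#' @export
affine_identity <- function() {
  affine2d(cbind(diag(2), c(0, 0)))
}

#' Apply an affine transform to points
#' @param transform An `affine2d`.
#' @param points n x 2 matrix (or length-2 vector) of coordinates (um).
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_affine <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 2) else as.matrix(points)
  out <- p %*% t(transform$matrix[, 1:2]) +
    matrix(transform$matrix[, 3], nrow(p), 2, byrow = TRUE)
  if (vec) drop(out) else { colnames(out) <- c("x", "y"); out }
}

#' Compose two affine transforms
#'
#' `compose_affine(outer, inner)` maps `x` to `outer(inner(x))`.
#'
#' @param outer,inner `affine2d` objects.
#' @return An `affine2d`.
#' @export
compose_affine <- function(outer, inner) {
  A <- outer$matrix[, 1:2]; a <- outer$matrix[, 3]
  B <- inner$matrix[, 1:2]; b <- inner$matrix[, 3]
  affine2d(cbind(A %*% B, A %*% b + a))
}

#' Invert an affine transform
#' @param transform An `affine2d`.
#' @return An `affine2d` with `compose_affine(transform, result)` = identity.
#' @export
invert_affine <- function(transform) {
  A <- transform$matrix[, 1:2]
  Ai <- solve(A)
  affine2d(cbind(Ai, -Ai %*% transform$matrix[, 3]))
}

#' @export
print.affine2d <- function(x, ...) {
  cat("2D affine transform (um):\n")
  print(round(x$matrix, 6))
  if (!is.null(attr(x, "rms"))) {
    cat("  landmark residual RMS:", format(attr(x, "rms"), digits = 4), "um\n")
  }
  invisible(x)
}

#' Fit an affine transform to landmark pairs by least squares
#'
#' Minimises the sum of squared residuals between transformed source and
#' target landmarks. All landmark kinds (radial vessels, surface vessels,
#' apical dendrites) are weighted equally.
#'
#' @param pairs Data frame with columns `xa`, `ya` (source) and `xb`, `yb`
#'   (target), or matrices via `source`/`target` columns.
#' @return An `affine2d` with attribute `rms` (residual root-mean-square,
#'   um).
#' @export
fit_affine <- function(pairs) {
  src <- cbind(pairs$xa, pairs$ya)
  tgt <- cbind(pairs$xb, pairs$yb)
  if (nrow(src) < 3) {
    stop("at least 3 landmark pairs are required (got ", nrow(src), ")")
  }
  X <- cbind(src, 1)
  qrX <- qr(X)
  if (qrX$rank < 3) {
    stop("landmark sources are collinear or coincident; the affine fit is ",
         "rank-deficient")
  }
  beta <- qr.coef(qrX, tgt)            # 3 x 2
  M <- rbind(cbind(t(beta[1:2, ]), beta[3, ]))
  fit <- affine2d(M)
  resid <- tgt - X %*% beta
  attr(fit, "rms") <- sqrt(mean(rowSums(resid^2)))
  fit
}

#' Compose pairwise section alignments into surface-frame transforms
#'
#' Fits the deeper-to-shallower affine for each adjacent section pair and
#' composes them so that section k maps through k-1, ..., 1 into the
#' surface frame. Section 0 receives the identity.
#'
#' @param stack A `section_stack` (see [make_section_stack()]) or a list
#'   with `sections` and per-pair `landmarks`.
#' @return List of `affine2d`, one per section, named by section index.
#' @export
flatten_stack <- function(stack) {
  n <- length(stack$sections)
  out <- vector("list", n)
  out[[1]] <- affine_identity()
  acc <- affine_identity()
  for (k in seq_len(n - 1)) {
    fit <- tryCatch(fit_affine(stack$landmarks[[k]]),
                    error = function(e) {
                      stop("section pair ", k, " -> ", k - 1, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    acc <- compose_affine(acc, fit)
    out[[k + 1]] <- acc
  }
  names(out) <- as.character(stack$sections)
  out
}

#' Warp an in-vivo area map into tissue coordinates
#'
#' Fits an affine from surface-vessel landmark pairs (map frame to tissue
#' frame) and applies it to every polygon vertex. Area names and order are
#' preserved; post-warp geometry is re-validated and self-intersections are
#' reported as warnings naming the offending area.
#'
#' @param map A `flatmap_parcellation`.
#' @param pairs Landmark data frame (`xa`, `ya` = map frame; `xb`, `yb` =
#'   tissue frame); at least 3 pairs.
#' @return The warped `flatmap_parcellation` (attribute `transform` holds
#'   the fitted `affine2d`).
#' @export
warp_map <- function(map, pairs) {
  fit <- fit_affine(pairs)
  areas <- lapply(map$areas, function(p) apply_affine(fit, p))
  for (nm in names(areas)) {
    if (!polygon_is_simple(areas[[nm]])) {
      warning("warped polygon for area '", nm, "' is self-intersecting")
    }
  }
  out <- flatmap_parcellation(map$animal_id, areas, validate = FALSE)
  attr(out, "transform") <- fit
  out
}
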