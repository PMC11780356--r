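# Flatmap parcellation: an ordered set of named, non-overlapping polygons
# (um) representing V1, the higher visual areas and surrounding non-visual
# areas on the cortical surface, per animal.

#' Area-name vocabularies
#'
#' `VISUAL_AREAS` are the mapped visual areas (V1 plus the five target
#' HVAs); `HVA_NAMES` are the five higher visual areas targeted for
#' tracing and used as the shuffle candidate set.
#'
#' @format Character vectors.
#' @export
VISUAL_AREAS <- c("V1", "PM", "AM", "RL", "AL", "LM")

#' @rdname VISUAL_AREAS
#' @export
HVA_NAMES <- c("PM", "AM", "RL", "AL", "LM")

#' Construct a flatmap parcellation
#'
#' @param animal_id Animal identifier.
#' @param areas Named list of two-column vertex matrices (um), in a fixed,
#'   meaningful order (the order is the deterministic tie-break for points
#'   on shared boundaries).
#' @param validate Check simplicity and pairwise interior disjointness?
#' @return An object of class `flatmap_parcellation`.
#' @export
flatmap_parcellation <- function(animal_id, areas, validate = TRUE) {
  stopifnot(is.list(areas), !is.null(names(areas)), all(nzchar(names(areas))))
  areas <- lapply(areas, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  obj <- structure(list(animal_id = as.character(animal_id), areas = areas),
                   class = "flatmap_parcellation")
  if (validate) validate_parcellation(obj)
  obj
}

#' Validate a parcellation's geometry
#'
#' Checks that every polygon is simple and that interiors are pairwise
#' disjoint; errors name the offending area or pair.
#'
#' @param parc A `flatmap_parcellation`.
#' @return The parcellation, invisibly.
#' @export
validate_parcellation <- function(parc) {
  nm <- names(parc$areas)
  for (i in seq_along(parc$areas)) {
    p <- parc$areas[[i]]
    if (nrow(p) < 3) stop("area '", nm[i], "' has fewer than 3 vertices")
    if (!all(is.finite(p))) stop("area '", nm[i], "' has non-finite vertices")
    if (!polygon_is_simple(p)) stop("area '", nm[i], "' is self-intersecting")
  }
  if (length(parc$areas) > 1) {
    for (i in seq_len(length(parc$areas) - 1)) {
      for (j in (i + 1):length(parc$areas)) {
        if (!polygons_interiors_disjoint(parc$areas[[i]], parc$areas[[j]])) {
          stop("areas '", nm[i], "' and '", nm[j], "' overlap")
        }
      }
    }
  }
  invisible(parc)
}

#' @export
print.flatmap_parcellation <- function(x, ...) {
  cat("Flatmap parcellation for animal", x$animal_id, "\n")
  cat("  areas (in assignment order):", paste(names(x$areas), collapse = ", "), "\n")
  a <- vapply(x$areas, polygon_area, numeric(1)) / 1e6
  cat("  total mapped surface:", format(sum(a), digits = 4), "mm^2\n")
  invisible(x)
}

#' Centroid of a named area in a parcellation
#' @param parc A `flatmap_parcellation`.
#' @param area Area name.
#' @return Numeric length-2 (x, y) in um.
#' @export
area_centroid <- function(parc, area) {
  if (!area %in% names(parc$areas)) {
    stop("area '", area, "' not present in map for animal '",
         parc$animal_id, "'")
  }
  polygon_centroid(parc$areas[[area]])
}

# Template schematic: a conforming mesh of 11 areas (V1, the five target
# HVAs, and five surrounding non-visual areas) over roughly 5 x 2.8 mm of
# flattened cortex. Vertices on shared boundaries are listed explicitly in
# every polygon that uses them, so joint vertex jitter preserves the
# non-overlap topology.
#' Template flatmap polygons
#'
#' @return Named list of polygon vertex matrices (um) for the schematic
#'   11-area map, in assignment order.
#' @export
template_flatmap_areas <- function() {
  P <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                            dimnames = list(NULL, c("x", "y")))
  list(
    V1  = P(0, 0,     1800, 0,    1800, 1200, 1800, 2000, 0, 2000, 0, 1200),
    PM  = P(0, 2000,  1800, 2000, 1800, 2800, 0, 2800),
    AM  = P(1800, 2000, 2600, 2000, 2600, 2800, 1800, 2800),
    RL  = P(2600, 1200, 3400, 1200, 3400, 2000, 2600, 2000),
    AL  = P(1800, 1200, 2600, 1200, 2600, 2000, 1800, 2000),
    LM  = P(1800, 0,   2600, 0,   2600, 1200, 1800, 1200),
    RSP = P(-800, 0,   0, 0,      0, 1200,   0, 2000,   0, 2800, -800, 2800),
    SS  = P(2600, 2000, 3400, 2000, 4200, 2000, 4200, 2800, 2600, 2800),
    PPC = P(3400, 1200, 4200, 1200, 4200, 2000, 3400, 2000),
    AUD = P(3400, 0,   4200, 0,   4200, 1200, 3400, 1200),
    TEa = P(2600, 0,   3400, 0,   3400, 1200, 2600, 1200)
  )
}
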