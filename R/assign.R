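# Assignment of labelled cells to cortical areas (point-in-polygon on the
# warped map) and layers (depth against the L5 marker band), starter-cell
# tabulation across thalamic nuclei, and per-experiment QC.

#' Assign cells to cortical areas
#'
#' Each cell receives the name of the parcellation polygon containing its
#' surface-frame position. Points on a shared boundary are assigned to the
#' first area in the parcellation's fixed order (deterministic tie-break);
#' cells outside all polygons are labelled `"unassigned"`.
#'
#' @param cells Data frame with `x_um`, `y_um`.
#' @param parcellation A `flatmap_parcellation`.
#' @return `cells` with an `area` column.
#' @export
assign_area <- function(cells, parcellation) {
  area <- rep("unassigned", nrow(cells))
  open <- rep(TRUE, nrow(cells))
  for (nm in names(parcellation$areas)) {
    if (!any(open)) break
    hit <- points_in_polygon(cells$x_um[open], cells$y_um[open],
                             parcellation$areas[[nm]], boundary = TRUE)
    area[open][hit] <- nm
    open[open][hit] <- FALSE
  }
  cells$area <- area
  cells
}

#' Layer band model for the L5 marker (Ctip2) band
#'
#' @param l5_top_um,l5_bottom_um Depth (um below pia) of the top and bottom
#'   of the L5 marker band; intervals are half-open `[top, bottom)`.
#' @return A `layer_bands` object.
#' @export
layer_bands <- function(l5_top_um = 550, l5_bottom_um = 700) {
  if (!(0 < l5_top_um && l5_top_um < l5_bottom_um)) {
    stop("need 0 < l5_top_um < l5_bottom_um")
  }
  structure(list(l5_top_um = l5_top_um, l5_bottom_um = l5_bottom_um),
            class = "layer_bands")
}

#' Assign cells to cortical layers by depth
#'
#' Half-open convention: depth < top is L2/3, `[top, bottom)` is L5, and
#' depth >= bottom is L6. Cells with missing depth are left `"unassigned"`
#' with a warning.
#'
#' @param cells Data frame with `depth_um`.
#' @param bands A `layer_bands` model.
#' @return `cells` with a `layer` column.
#' @export
assign_layer <- function(cells, bands) {
  d <- cells$depth_um
  layer <- rep("unassigned", nrow(cells))
  ok <- !is.na(d)
  if (any(!ok)) warning(sum(!ok), " cell(s) have missing depth; left unassigned")
  layer[ok & d < bands$l5_top_um] <- "L23"
  layer[ok & d >= bands$l5_top_um & d < bands$l5_bottom_um] <- "L5"
  layer[ok & d >= bands$l5_bottom_um] <- "L6"
  cells$layer <- layer
  cells
}

#' Tabulate starter cells across thalamic nuclei
#'
#' @param counts Named nonnegative integer vector of starter counts per
#'   nucleus.
#' @return Data frame with `nucleus`, `count`, `fraction` and `percent`
#'   (percent of total starters, rounded to one decimal as printed).
#' @export
tabulate_starters <- function(counts) {
  if (any(counts < 0)) stop("starter counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("no starter cells recorded (empty experiment)")
  frac <- counts / total
  data.frame(nucleus = names(counts),
             count = as.integer(counts),
             fraction = as.numeric(frac),
             percent = round(100 * as.numeric(frac), 1),
             row.names = NULL)
}

#' Quality-control check of an experiment's starter distribution
#'
#' Fails experiments whose pulvinar starter fraction falls below a
#' configurable threshold (targeting bias towards neighbouring nuclei). The
#' default threshold is an artifact convention, not a value from any
#' particular study.
#'
#' @param experiment A `trio_experiment` (or any list with `$starters`).
#' @param min_pulvinar_fraction Minimum acceptable pulvinar fraction.
#' @return List with `pass` (logical), `pulvinar_fraction` and `reasons`.
#' @export
qc_experiment <- function(experiment, min_pulvinar_fraction = 0.5) {
  st <- experiment$starters
  if (is.null(st) || sum(st) == 0) {
    return(list(pass = FALSE, pulvinar_fraction = NA_real_,
                reasons = "no starter cells recorded"))
  }
  pf <- unname(st[["pulvinar"]] / sum(st))
  reasons <- character(0)
  if (pf < min_pulvinar_fraction) {
    reasons <- sprintf("starter bias: pulvinar fraction %.3f < %.3f",
                       pf, min_pulvinar_fraction)
  }
  list(pass = length(reasons) == 0, pulvinar_fraction = pf, reasons = reasons)
}
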