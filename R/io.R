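# File formats: cell tables as CSV, parcellations as GeoJSON, landmark
# pairs as CSV, results as JSON. Readers validate schemas; writers stamp a
# schema version.

CELLS_SCHEMA <- c("cell_id", "animal_id", "target", "x_um", "y_um",
                  "section", "depth_um", "layer", "area", "channel")
CELLS_NUMERIC <- c("x_um", "y_um", "section", "depth_um")
SCHEMA_VERSION <- "1"

#' Write a cell table to CSV
#' @param cells Data frame with the standard cell columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  missing <- setdiff(CELLS_SCHEMA, names(cells))
  if (length(missing)) {
    stop("cell table is missing column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(cells[, CELLS_SCHEMA, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Validates the header (missing or duplicated columns are schema errors)
#' and the numeric columns (a malformed row is reported by number).
#'
#' @param path CSV path.
#' @return Data frame of cell records.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  nm <- names(df)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicate column(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  missing <- setdiff(CELLS_SCHEMA, nm)
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  for (col in CELLS_NUMERIC) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad)) {
        stop("malformed value in column '", col, "' at data row ", bad[1],
             " of ", path)
      }
      df[[col]] <- coerced
    }
  }
  df[, CELLS_SCHEMA, drop = FALSE]
}

#' Write a parcellation as GeoJSON
#'
#' One Polygon feature per area, in parcellation order, with `name` and
#' `animal_id` properties; coordinates in um.
#'
#' @param parc A `flatmap_parcellation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  features <- lapply(names(parc$areas), function(nm) {
    p <- parc$areas[[nm]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = nm, animal_id = parc$animal_id,
                           schema_version = SCHEMA_VERSION),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parcellation from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with a `name` property;
#' feature order defines the area (tie-break) order. Overlapping polygons
#' are a validation error naming the pair.
#'
#' @param path GeoJSON path.
#' @param validate Re-validate geometry on read?
#' @return A `flatmap_parcellation`.
#' @export
read_parcellation <- function(path, validate = TRUE) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop(path, " is not a GeoJSON FeatureCollection")
  }
  animal <- "unknown"
  areas <- list()
  for (ft in gj$features) {
    if (!identical(ft$geometry$type, "Polygon")) {
      stop("non-Polygon geometry ('", ft$geometry$type %||% "missing",
           "') in ", path)
    }
    nm <- ft$properties$name
    if (is.null(nm)) stop("feature without a 'name' property in ", path)
    if (!is.null(ft$properties$animal_id)) animal <- ft$properties$animal_id
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    areas[[nm]] <- m
  }
  flatmap_parcellation(animal, areas, validate = validate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write landmark pairs to CSV
#' @param pairs Landmark data frame (`section_a`, `xa`, `ya`, `section_b`,
#'   `xb`, `yb`, `kind`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' Read landmark pairs from CSV
#' @param path CSV path.
#' @return Landmark data frame.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_a", "xa", "ya", "section_b", "xb", "yb")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df
}
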