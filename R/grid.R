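#' Regular longitude/latitude grid geometry
#'
#' Describes a regular grid of square cells (in degrees). Cells are indexed
#' row-major with 1-based ids; row 1 is the northernmost row, matching the
#' reading order of ESRI ASCII grids. `origin_lon`/`origin_lat` are the
#' lower-left (south-west) outer corner of the grid.
#'
#' @param n_rows,n_cols Number of rows/columns (>= 1).
#' @param cell_size Cell edge length in degrees (same in both axes).
#' @param origin_lon,origin_lat Lower-left corner of the grid, degrees.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(60, 84, 2.5 / 60, -74, -41)
#' cell_center(g, 1)
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size, origin_lon, origin_lat) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size),
      origin_lon = as.numeric(origin_lon), origin_lat = as.numeric(origin_lat)
    ),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "grid_geometry: %d x %d cells of %.6g deg, lower-left (%.6g, %.6g)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat
  ))
  invisible(x)
}

#' Test whether two grid geometries are aligned
#'
#' Two rasters are aligned iff all geometry fields agree (row/column counts,
#' cell size, and origin, the latter two within a 1e-9 degree tolerance).
#'
#' @param a,b `grid_geometry` objects.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < 1e-9 &&
    abs(a$origin_lon - b$origin_lon) < 1e-9 &&
    abs(a$origin_lat - b$origin_lat) < 1e-9
}

n_cells <- function(geometry) geometry$n_rows * geometry$n_cols

#' Longitude/latitude of cell centers
#'
#' @param geometry A `grid_geometry`.
#' @param cells Integer vector of 1-based row-major cell ids.
#' @return Data frame with columns `longitude`, `latitude`.
#' @export
cell_center <- function(geometry, cells) {
  stopifnot(all(cells >= 1), all(cells <= n_cells(geometry)))
  row <- (cells - 1L) %/% geometry$n_cols + 1L
  col <- (cells - 1L) %% geometry$n_cols + 1L
  top <- geometry$origin_lat + geometry$n_rows * geometry$cell_size
  data.frame(
    longitude = geometry$origin_lon + (col - 0.5) * geometry$cell_size,
    latitude = top - (row - 0.5) * geometry$cell_size
  )
}

#' Continuous suitability raster
#'
#' A continuous model-output surface on a regular grid. `values` is an
#' `n_rows x n_cols` matrix whose first row is the northernmost; `NA`
#' encodes nodata. At least one finite value is required.
#'
#' @param geometry A `grid_geometry`.
#' @param values Numeric matrix of per-cell values (`NA` = nodata).
#' @param name Optional layer name.
#' @return An object of class `enm_raster`.
#' @export
enm_raster <- function(geometry, values, name = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols) {
    stop("values matrix does not match the grid geometry", call. = FALSE)
  }
  if (!any(is.finite(values))) {
    stop("raster has no finite values", call. = FALSE)
  }
  structure(list(geometry = geometry, values = values, name = name),
    class = "enm_raster"
  )
}

#' @export
print.enm_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "enm_raster%s: %d x %d cells, %d nodata, range [%.4g, %.4g]\n",
    if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
    x$geometry$n_rows, x$geometry$n_cols, sum(!is.finite(x$values)),
    min(v), max(v)
  ))
  invisible(x)
}

#' Binary (suitable/unsuitable) map with threshold provenance
#'
#' @param geometry A `grid_geometry`.
#' @param suitable Logical matrix (`NA` = nodata).
#' @param threshold_value Numeric threshold the map was cut at (`NA` when
#'   unknown, e.g. a map read from disk).
#' @param omission_tolerance Calibration omission tolerance in `[0, 1)` used
#'   to derive the threshold (`NA` when not applicable).
#' @param source Character label recording where the threshold came from.
#' @return An object of class `enm_binary`.
#' @export
enm_binary <- function(geometry, suitable, threshold_value = NA_real_,
                       omission_tolerance = NA_real_, source = "unknown") {
  stopifnot(inherits(geometry, "grid_geometry"))
  suitable <- as.matrix(suitable)
  storage.mode(suitable) <- "logical"
  if (nrow(suitable) != geometry$n_rows || ncol(suitable) != geometry$n_cols) {
    stop("suitable matrix does not match the grid geometry", call. = FALSE)
  }
  structure(
    list(
      geometry = geometry, suitable = suitable,
      threshold_value = threshold_value,
      omission_tolerance = omission_tolerance, source = source
    ),
    class = "enm_binary"
  )
}

#' @export
print.enm_binary <- function(x, ...) {
  cat(sprintf(
    "enm_binary: %d x %d cells, %d suitable of %d usable (threshold %.6g, tolerance %s)\n",
    x$geometry$n_rows, x$geometry$n_cols,
    sum(x$suitable, na.rm = TRUE), sum(!is.na(x$suitable)),
    x$threshold_value,
    ifelse(is.na(x$omission_tolerance), "NA",
      format(x$omission_tolerance)
    )
  ))
  invisible(x)
}

#' Cut a continuous raster at a fixed threshold
#'
#' Cells with value `>= threshold` become suitable (closed at the
#' threshold); nodata cells stay nodata.
#'
#' @param pred An `enm_raster`.
#' @param threshold Numeric cut point.
#' @param source Provenance label stored on the result.
#' @return An `enm_binary`.
#' @export
binarize <- function(pred, threshold, source = "fixed") {
  stopifnot(inherits(pred, "enm_raster"), is.finite(threshold))
  suit <- pred$values >= threshold
  suit[!is.finite(pred$values)] <- NA
  enm_binary(pred$geometry, suit,
    threshold_value = threshold,
    omission_tolerance = NA_real_, source = source
  )
}
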