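#' Map occurrence records to grid cells
#'
#' Each record is assigned to the cell whose half-open interval
#' `[edge, edge + cell_size)` (in both longitude and latitude, anchored at
#' the grid's lower-left corner) contains it, so a point exactly on a
#' cell's lower-left corner belongs to that cell. Records outside the grid
#' extent are flagged (`inside = FALSE`), never silently dropped.
#'
#' @param occ Occurrence data frame (`longitude`, `latitude`).
#' @param geometry A [grid_geometry()].
#' @return Data frame with one row per record: `row`, `col`, `cell`
#'   (1-based row-major id, `NA` when outside) and `inside`.
#' @export
assign_cells <- function(occ, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  cs <- geometry$cell_size
  col <- floor((occ$longitude - geometry$origin_lon) / cs) + 1
  row_s <- floor((occ$latitude - geometry$origin_lat) / cs) + 1 # from south
  inside <- col >= 1 & col <= geometry$n_cols &
    row_s >= 1 & row_s <= geometry$n_rows
  row <- geometry$n_rows - row_s + 1
  cell <- ifelse(inside, (row - 1) * geometry$n_cols + col, NA_real_)
  data.frame(
    row = ifelse(inside, row, NA_integer_),
    col = ifelse(inside, col, NA_integer_),
    cell = as.integer(cell), inside = inside
  )
}

#' Thin occurrences to one record per grid cell
#'
#' Spatial thinning against a regular degree grid anchored at
#' (-180, -90): at most one record is kept per `cell_size` cell, the
#' first in input order. Thinning is idempotent and order-stable.
#'
#' @param occ Occurrence data frame (`longitude`, `latitude`, ...).
#' @param cell_size Thinning cell edge in degrees (e.g. `2.5 / 60` for a
#'   2.5-arc-minute grid).
#' @param origin Anchor corner of the thinning grid, default `c(-180, -90)`
#'   (the tiling convention of global bioclimatic layers).
#' @return The thinned data frame (all original columns, original order).
#' @examples
#' occ <- data.frame(longitude = c(0.01, 0.02, 0.9), latitude = c(0, 0, 0))
#' nrow(thin_to_grid(occ, 0.5)) # 2: first two share a 0.5-degree cell
#' @export
thin_to_grid <- function(occ, cell_size, origin = c(-180, -90)) {
  stopifnot(cell_size > 0)
  if (nrow(occ) == 0) {
    return(occ)
  }
  key <- paste(
    floor((occ$longitude - origin[1]) / cell_size),
    floor((occ$latitude - origin[2]) / cell_size)
  )
  occ[!duplicated(key), , drop = FALSE]
}

# Resolve occurrences to usable cells of a raster: inside the extent and
# on non-nodata cells. Off-grid and nodata records are excluded with a
# warning (coastal records commonly fall off rasterized land), and the
# counts are reported so downstream reports can surface them.
occurrence_cells <- function(occ, raster, what = "occurrence") {
  a <- assign_cells(occ, raster$geometry)
  vals <- rep(NA_real_, nrow(a))
  vals[a$inside] <- raster$values[cbind(a$row[a$inside], a$col[a$inside])]
  usable <- a$inside & is.finite(vals)
  n_out <- sum(!a$inside)
  n_nd <- sum(a$inside & !is.finite(vals))
  if (n_out + n_nd > 0) {
    warning(
      sprintf(
        "%d %s record(s) excluded: %d outside the grid, %d on nodata cells",
        n_out + n_nd, what, n_out, n_nd
      ),
      call. = FALSE
    )
  }
  list(
    cell = a$cell[usable], value = vals[usable],
    n_usable = sum(usable), n_outside = n_out, n_nodata = n_nd
  )
}
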