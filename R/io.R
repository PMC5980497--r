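#' Read an occurrence table from CSV
#'
#' Expects a header with `longitude`, `latitude` and (optionally)
#' `population` columns; extra columns are ignored. Rows with unparseable
#' or out-of-range coordinates (|lon| > 180, |lat| > 90) are rejected with
#' a warning listing their row numbers; valid rows are returned in file
#' order. Records without a population label get `"other"`.
#'
#' @param path CSV file path.
#' @param lon_col,lat_col,pop_col Column names to use.
#' @return Data frame with columns `longitude`, `latitude`, `population`
#'   and an attribute `rejected_rows` (integer vector of 1-based data-row
#'   numbers that were dropped).
#' @export
read_occurrences <- function(path, lon_col = "longitude",
                             lat_col = "latitude", pop_col = "population") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(lon_col, lat_col) %in% names(raw))) {
    stop(
      sprintf(
        "occurrence file '%s' lacks mandatory columns '%s', '%s'",
        path, lon_col, lat_col
      ),
      call. = FALSE
    )
  }
  lon <- suppressWarnings(as.numeric(raw[[lon_col]]))
  lat <- suppressWarnings(as.numeric(raw[[lat_col]]))
  pop <- if (pop_col %in% names(raw)) as.character(raw[[pop_col]]) else
    rep("other", nrow(raw))
  pop[is.na(pop) | pop == ""] <- "other"
  bad <- which(is.na(lon) | is.na(lat) | abs(lon) > 180 | abs(lat) > 90)
  if (length(bad) > 0) {
    warning(
      sprintf(
        "rejected %d occurrence row(s) with invalid coordinates: %s",
        length(bad), paste(bad, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- data.frame(
    longitude = lon[keep], latitude = lat[keep],
    population = pop[keep], stringsAsFactors = FALSE
  )
  attr(out, "rejected_rows") <- as.integer(bad)
  out
}

#' Write an occurrence table to CSV
#'
#' @param occ Occurrence data frame (`longitude`, `latitude`, `population`).
#' @param path Output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(
    occ[, c("longitude", "latitude", "population")],
    path,
    row.names = FALSE, quote = FALSE
  )
}

# ESRI ASCII grid ("Arc/Info ASCII") input/output. The format is a
# 5-6 line plain-text header (ncols, nrows, xllcorner, yllcorner,
# cellsize, optional NODATA_value) followed by the values north-to-south.
# Values are written with 17 significant digits so the round trip is
# bit-exact for doubles.

#' Read an ESRI ASCII grid raster
#'
#' Only square-cell grids are supported; headers declaring separate `dx`
#' and `dy` cell sizes are rejected. `xllcenter`/`yllcenter` headers are
#' converted to corner coordinates.
#'
#' @param path `.asc` file path.
#' @param name Optional layer name to attach.
#' @return An [enm_raster()].
#' @export
read_ascii_raster <- function(path, name = NULL) {
  lines <- readLines(path, n = 7L)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != 2 ||
      is.na(suppressWarnings(as.numeric(parts[2])))) {
      break
    }
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    n_header <- n_header + 1L
  }
  if (any(c("dx", "dy") %in% names(header))) {
    stop("non-uniform cell size (dx/dy header) is unsupported", call. = FALSE)
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(header))) {
    stop(sprintf("'%s' is not an ESRI ASCII grid", path), call. = FALSE)
  }
  nc <- as.integer(header$ncols)
  nr <- as.integer(header$nrows)
  cs <- header$cellsize
  xll <- if (!is.null(header$xllcorner)) header$xllcorner else
    header$xllcenter - cs / 2
  yll <- if (!is.null(header$yllcorner)) header$yllcorner else
    header$yllcenter - cs / 2
  if (is.null(xll) || is.null(yll)) {
    stop(sprintf("'%s' lacks xll/yll header fields", path), call. = FALSE)
  }
  vals <- scan(path, what = numeric(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(
      sprintf(
        "'%s': expected %d values, found %d", path, nr * nc, length(vals)
      ),
      call. = FALSE
    )
  }
  if (!is.null(header$nodata_value)) {
    vals[vals == header$nodata_value] <- NA_real_
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  enm_raster(grid_geometry(nr, nc, cs, xll, yll), m, name = name)
}

#' Write an ESRI ASCII grid raster
#'
#' @param raster An [enm_raster()].
#' @param path Output path.
#' @param nodata Value standing in for `NA` cells.
#' @export
write_ascii_raster <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "enm_raster"))
  g <- raster$geometry
  v <- raster$values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin_lon),
    sprintf("yllcorner %.17g", g$origin_lat),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", nodata)
  ), con)
  for (r in seq_len(g$n_rows)) {
    writeLines(paste(sprintf("%.17g", v[r, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a binary (0/1) map from an ESRI ASCII grid
#'
#' The threshold provenance of a map read from disk is unknown; it is
#' recorded as `NA` with source `"file"`.
#'
#' @param path `.asc` file path.
#' @return An [enm_binary()].
#' @export
read_binary_map <- function(path) {
  r <- read_ascii_raster(path)
  v <- r$values
  ok <- is.na(v) | v %in% c(0, 1)
  if (!all(ok)) {
    stop(sprintf("'%s' is not a 0/1 raster", path), call. = FALSE)
  }
  enm_binary(r$geometry, v == 1, source = "file")
}

#' Write a binary map as a 0/1 integer ESRI ASCII grid
#'
#' @param bin An [enm_binary()].
#' @param path Output path.
#' @export
write_binary_map <- function(bin, path) {
  stopifnot(inherits(bin, "enm_binary"))
  write_ascii_raster(
    enm_raster(bin$geometry, ifelse(is.na(bin$suitable), NA_real_,
      as.numeric(bin$suitable)
    )),
    path
  )
}
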