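# Shared fixtures. Scenarios are cached across test files (helpers are
# sourced once per test run), keyed by seed; everything is deterministic.

.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(seed) {
  key <- as.character(seed)
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- generate_scenario(seed)
  }
  .scenario_cache[[key]]
}

small_geom <- function(n = 10) grid_geometry(n, n, 0.5, 0, 0)

# raster with values laid out row-major from a vector
small_raster <- function(v, n = 10) {
  enm_raster(small_geom(n), matrix(v, n, n, byrow = TRUE))
}

# occurrences at the centers of the given 1-based row-major cell ids
occ_at_cells <- function(geometry, cells, population = "other") {
  cc <- cell_center(geometry, cells)
  data.frame(
    longitude = cc$longitude, latitude = cc$latitude,
    population = population, stringsAsFactors = FALSE
  )
}

# i.i.d. uniform suitability raster with uniformly placed test points,
# the null configuration for partial ROC
null_proc_case <- function(seed, n_cells_side = 100, n_test = 50) {
  g <- grid_geometry(n_cells_side, n_cells_side, 0.1, 0, 0)
  withr::with_seed(seed, {
    vals <- matrix(
      stats::runif(n_cells_side^2), n_cells_side,
      n_cells_side
    )
    cells <- sample.int(n_cells_side^2, n_test)
    list(pred = enm_raster(g, vals), test = occ_at_cells(g, cells))
  })
}
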