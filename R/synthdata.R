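# Synthetic virtual-species scenarios: correlated environmental layers,
# a Gaussian true niche, geographically disjoint calibration populations
# with a held-out central evaluation population, and contrasting
# pseudo-model suitability surfaces. Every artifact is a pure function of
# (seed, configuration).

default_geometry <- function() {
  # 3.5 x 2.5 degree coastal-Chile-like extent at 2.5 arc-minutes
  grid_geometry(
    n_rows = 60, n_cols = 84, cell_size = 2.5 / 60,
    origin_lon = -74, origin_lat = -41
  )
}

# Smooth random field on the grid: a low-frequency random cosine series
# plus a random linear lon/lat gradient, standardized to mean 0, sd 1.
# Draws come from the caller's RNG stream.
smooth_field <- function(geometry, n_waves = 12, gradient_sd = 1) {
  nr <- geometry$n_rows
  nc <- geometry$n_cols
  u <- matrix((seq_len(nc) - 0.5) / nc, nr, nc, byrow = TRUE)
  v <- matrix((nr - seq_len(nr) + 0.5) / nr, nr, nc) # increases northwards
  f <- matrix(0, nr, nc)
  amp <- stats::rnorm(n_waves)
  fu <- stats::runif(n_waves, -2.5, 2.5)
  fv <- stats::runif(n_waves, -2.5, 2.5)
  ph <- stats::runif(n_waves, 0, 2 * pi)
  for (k in seq_len(n_waves)) {
    f <- f + amp[k] * cos(2 * pi * (fu[k] * u + fv[k] * v) + ph[k])
  }
  grad <- stats::rnorm(2, sd = gradient_sd)
  f <- f + grad[1] * u + grad[2] * v
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic environmental raster stack
#'
#' Each layer is a smooth random surface (low-frequency cosine series
#' plus a random latitudinal/longitudinal gradient). Pairwise layer
#' correlation is controlled by blending a shared latent field with
#' weight `layer_correlation` against an independent field per layer
#' (`sqrt(w) * latent + sqrt(1 - w) * own`), so the expected pairwise
#' correlation is approximately `layer_correlation`. The default 0.82
#' mimics the strong collinearity of bioclimatic variables and yields a
#' three-component space at the default 90% retention. Layers get
#' arbitrary per-layer offsets and scales, mimicking the incommensurate
#' units of bioclimatic variables. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param geometry A [grid_geometry()]; default 60 x 84 cells of 2.5
#'   arc-minutes.
#' @param n_layers Number of layers (>= 2, default 8).
#' @param layer_correlation Blend weight in `[0, 1]` (default 0.82).
#' @return An [env_stack()].
#' @export
generate_env_stack <- function(seed, geometry = NULL, n_layers = 8,
                               layer_correlation = 0.82) {
  stopifnot(n_layers >= 2, layer_correlation >= 0, layer_correlation <= 1)
  if (is.null(geometry)) geometry <- default_geometry()
  withr::with_seed(seed, {
    latent <- smooth_field(geometry)
    layers <- vector("list", n_layers)
    for (i in seq_len(n_layers)) {
      own <- smooth_field(geometry)
      f <- sqrt(layer_correlation) * latent +
        sqrt(1 - layer_correlation) * own
      mu <- stats::runif(1, 0, 20)
      sig <- stats::runif(1, 1, 5)
      layers[[i]] <- mu + sig * f
    }
    names(layers) <- sprintf("env%02d", seq_len(n_layers))
    env_stack(geometry, layers)
  })
}

scenario_bands <- function(n_rows) {
  list(
    north = seq_len(floor(0.30 * n_rows)),
    central = seq(round(0.35 * n_rows) + 1, round(0.65 * n_rows)),
    south = seq(n_rows - floor(0.30 * n_rows) + 1, n_rows)
  )
}

#' Generate the true niche and occurrence populations
#'
#' The true niche is a Gaussian (bell-shaped) suitability response in
#' standardized layer space: `suitability = exp(-m/2)` with `m` the
#' squared distance to the niche center divided by `niche_breadth^2`.
#' The center is the mean environment of three anchor cells, one at the
#' middle of each latitudinal band, so that all three bands contain
#' suitable cells. Occurrences are sampled per band,
#' suitability-weighted and without replacement over cells whose true
#' suitability exceeds `suitability_floor` (so the occurrence sets are
#' already thinned to one record per cell). The northern and southern
#' bands are the geographically disjoint calibration populations; the
#' central band is the held-out evaluation population.
#'
#' @param stack An [env_stack()] (typically from
#'   [generate_env_stack()]).
#' @param seed Integer seed.
#' @param niche_breadth Niche half-width in background standard
#'   deviations (default 3.5).
#' @param counts Named occurrence counts `c(north, central, south)`,
#'   default `c(42, 7, 61)`.
#' @param suitability_floor Minimum true suitability of occurrence cells
#'   (default 0.5).
#' @return List with `truth` (an [enm_raster()] of true suitability),
#'   `occurrences` (data frame with `population` in
#'   north/central/south), `true_niche` (the 0.5-suitability contour as
#'   an [ellipsoid()] in standardized layer space), `bands`, and the
#'   parameters used.
#' @export
generate_truth_and_occurrences <- function(stack, seed, niche_breadth = 3.5,
                                           counts = c(
                                             north = 42, central = 7,
                                             south = 61
                                           ),
                                           suitability_floor = 0.5) {
  stopifnot(inherits(stack, "env_stack"), all(counts > 0))
  if (is.null(names(counts))) names(counts) <- c("north", "central", "south")
  g <- stack$geometry
  sm <- stack_matrix(stack)
  Z <- scale(sm$X)
  bands <- scenario_bands(g$n_rows)
  mid_cell <- function(rows) {
    (rows[ceiling(length(rows) / 2)] - 1) * g$n_cols + ceiling(g$n_cols / 2)
  }
  anchors <- vapply(bands, mid_cell, numeric(1))
  ai <- match(anchors, sm$cell_ids)
  if (any(is.na(ai))) stop("anchor cell falls on nodata", call. = FALSE)
  center <- colMeans(Z[ai, , drop = FALSE])
  m <- rowSums(sweep(Z, 2, center)^2) / niche_breadth^2
  suit <- exp(-m / 2)
  vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  vals[cbind(
    (sm$cell_ids - 1) %/% g$n_cols + 1,
    (sm$cell_ids - 1) %% g$n_cols + 1
  )] <- suit
  truth <- enm_raster(g, vals, name = "truth")
  cell_row <- (sm$cell_ids - 1) %/% g$n_cols + 1
  occ <- withr::with_seed(seed, {
    out <- list()
    for (b in names(bands)) {
      elig <- which(cell_row %in% bands[[b]] & suit > suitability_floor)
      if (length(elig) < counts[[b]]) {
        stop(
          sprintf(
            "infeasible: %d cells above the suitability floor in the %s band, %d occurrences requested",
            length(elig), b, counts[[b]]
          ),
          call. = FALSE
        )
      }
      picked <- elig[sample.int(length(elig), counts[[b]],
        prob = suit[elig]
      )]
      cc <- cell_center(g, sm$cell_ids[picked])
      out[[b]] <- data.frame(
        longitude = cc$longitude,
        latitude = cc$latitude,
        population = b, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  rownames(occ) <- NULL
  list(
    truth = truth, occurrences = occ,
    true_niche = ellipsoid(
      center,
      diag(length(center)) / (niche_breadth^2 * 2 * log(2))
    ),
    bands = bands, niche_breadth = niche_breadth, counts = counts,
    suitability_floor = suitability_floor, seed = as.integer(seed)
  )
}

#' Generate contrasting pseudo-model suitability rasters
#'
#' Stand-ins for the outputs of real niche-modeling algorithms, chosen to
#' span the behaviors the evaluation metrics must discriminate:
#' `matched` is the true suitability itself; `broad` is a monotone
#' flattening of the truth (`truth^0.1`, an overly permissive model);
#' `overfit` is the truth masked to a small geographic neighborhood of
#' the calibration (north + south) occurrence cells, zero elsewhere; and
#' `random` is i.i.d. uniform noise. Deterministic given the seed.
#'
#' @param stack The [env_stack()] of the scenario.
#' @param truth Result of [generate_truth_and_occurrences()].
#' @param seed Integer seed (used by the `random` model).
#' @param overfit_radius Chebyshev cell radius of the overfit
#'   neighborhood (default 2).
#' @return Named list of [enm_raster()]s: `matched`, `broad`, `overfit`,
#'   `random`.
#' @export
generate_pseudo_models <- function(stack, truth, seed, overfit_radius = 2) {
  g <- stack$geometry
  tv <- truth$truth$values
  calib <- truth$occurrences[truth$occurrences$population %in%
    c("north", "south"), ]
  a <- assign_cells(calib, g)
  mask <- matrix(FALSE, g$n_rows, g$n_cols)
  for (i in seq_len(nrow(a))) {
    rr <- max(1, a$row[i] - overfit_radius):min(g$n_rows, a$row[i] + overfit_radius)
    cc <- max(1, a$col[i] - overfit_radius):min(g$n_cols, a$col[i] + overfit_radius)
    mask[rr, cc] <- TRUE
  }
  over <- ifelse(mask, tv, 0)
  over[is.na(tv)] <- NA_real_
  rnd <- withr::with_seed(seed, {
    r <- matrix(stats::runif(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
    r[is.na(tv)] <- NA_real_
    r
  })
  list(
    matched = enm_raster(g, tv, name = "matched"),
    broad = enm_raster(g, tv^0.1, name = "broad"),
    overfit = enm_raster(g, over, name = "overfit"),
    random = enm_raster(g, rnd, name = "random")
  )
}

#' Generate a complete synthetic evaluation scenario
#'
#' Convenience wrapper tying the generator together: environmental stack,
#' true niche and occurrence populations, pseudo-models, the
#' principal-component environmental space, and the observed-niche MVE
#' fit to all occurrences projected into that space.
#'
#' @param seed Integer master seed (sub-stages use `seed`, `seed + 1`,
#'   `seed + 2`).
#' @param geometry Optional [grid_geometry()].
#' @param n_layers,layer_correlation Passed to [generate_env_stack()].
#' @param niche_breadth,counts,suitability_floor Passed to
#'   [generate_truth_and_occurrences()].
#' @param retention PCA retention fraction (default 0.90).
#' @return List of class `enm_scenario`.
#' @export
generate_scenario <- function(seed, geometry = NULL, n_layers = 8,
                              layer_correlation = 0.82, niche_breadth = 3.5,
                              counts = c(north = 42, central = 7, south = 61),
                              suitability_floor = 0.5, retention = 0.90) {
  stack <- generate_env_stack(seed, geometry, n_layers, layer_correlation)
  truth <- generate_truth_and_occurrences(stack, seed + 1,
    niche_breadth = niche_breadth,
    counts = counts, suitability_floor = suitability_floor
  )
  models <- generate_pseudo_models(stack, truth, seed + 2)
  space <- build_pca(stack, retention)
  oc <- occurrence_cells(truth$occurrences, truth$truth)
  observed <- fit_mve(space_scores(space, unique(oc$cell)))
  structure(
    list(
      seed = as.integer(seed), geometry = stack$geometry,
      stack = stack, space = space,
      truth = truth$truth, true_niche = truth$true_niche,
      occurrences = truth$occurrences, bands = truth$bands,
      pseudo_models = models, observed_mve = observed,
      config = list(
        n_layers = n_layers, layer_correlation = layer_correlation,
        niche_breadth = niche_breadth, counts = counts,
        suitability_floor = suitability_floor, retention = retention
      )
    ),
    class = "enm_scenario"
  )
}

#' @export
print.enm_scenario <- function(x, ...) {
  cat(sprintf(
    paste0(
      "enm_scenario (seed %d): %d x %d grid, %d layers, %d retained",
      " components\n  occurrences: %s\n  pseudo-models: %s\n"
    ),
    x$seed, x$geometry$n_rows, x$geometry$n_cols,
    length(x$stack$layers), x$space$d,
    paste(sprintf(
      "%s = %d", names(table(x$occurrences$population)),
      as.integer(table(x$occurrences$population))
    ), collapse = ", "),
    paste(names(x$pseudo_models), collapse = ", ")
  ))
  invisible(x)
}
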