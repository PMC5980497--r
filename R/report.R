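#' Run the full evaluation workflow over a set of models
#'
#' Ties the modules together in the calibrate/evaluate workflow: for each
#' continuous prediction, binary maps at the requested calibration
#' omission tolerances with omission rate, proportional suitable area and
#' the one-tailed cumulative binomial probability; bootstrap partial ROC
#' on the continuous output; an environmental-space report (index I
#' counts, Jaccard, extrapolation distance) on the first-tolerance binary
#' map; optional AIC given a parameter count; and an agreement ensemble
#' across models. Any per-model stage error is captured in that model's
#' entry without aborting the remaining models. Every number in the
#' report is reproducible from the configuration and master seed alone.
#'
#' @param config A list with entries:
#'   * `models`: named list of [enm_raster()]s or `.asc` file paths;
#'   * `stack`: an [env_stack()] (or omit and give `space`);
#'   * `space`: optionally a prebuilt [build_pca()] space;
#'   * `calib`: calibration occurrences (data frame or CSV path);
#'   * `test`: evaluation occurrences (data frame, CSV path, or `NULL`
#'     to skip the geographic-space metrics);
#'   * `observed_occ`: occurrences defining the observed niche MVE
#'     (default: calibration plus evaluation occurrences);
#'   * `omission`: omission tolerances (default `c(0, 0.05)`);
#'   * `proc`: list of partial-ROC settings `E`, `n_replicates`,
#'     `resample_fraction`;
#'   * `jaccard_mode`, `mc_samples`: E-space index II settings;
#'   * `aic`: optional named list, per model either `list(K =, lnL =)`
#'     or with `lnL = NULL` to compute the raster likelihood, plus
#'     optional `n` for AICc;
#'   * `seed`: integer master seed (default 42); per-model seeds are
#'     derived as `seed + 1000 * model_index`.
#' @param retention PCA retention when the space is built from `stack`.
#' @return List of class `enm_evaluation`.
#' @export
run_full_evaluation <- function(config, retention = 0.90) {
  stopifnot(is.list(config), length(config$models) >= 1)
  seed <- if (is.null(config$seed)) 42L else as.integer(config$seed)
  omission <- if (is.null(config$omission)) c(0, 0.05) else config$omission
  proc_cfg <- utils::modifyList(
    list(E = 0.05, n_replicates = 100L, resample_fraction = 0.5),
    if (is.null(config$proc)) list() else config$proc
  )
  jmode <- if (is.null(config$jaccard_mode)) {
    "ellipsoid_volume"
  } else {
    config$jaccard_mode
  }
  mc <- if (is.null(config$mc_samples)) 100000L else config$mc_samples

  load_occ <- function(x, what) {
    if (is.null(x)) {
      return(NULL)
    }
    if (is.character(x)) read_occurrences(x) else x
  }
  load_raster <- function(x, nm) {
    if (is.character(x)) read_ascii_raster(x, name = nm) else x
  }
  hash_of <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unname(tools::md5sum(x))
    } else {
      NA_character_
    }
  }

  calib <- load_occ(config$calib, "calibration")
  if (is.null(calib)) stop("config$calib is required", call. = FALSE)
  test <- load_occ(config$test, "evaluation")
  models <- lapply(
    seq_along(config$models),
    function(i) load_raster(config$models[[i]], names(config$models)[i])
  )
  names(models) <- names(config$models)
  hashes <- c(
    vapply(config$models, hash_of, character(1)),
    calib = hash_of(config$calib), test = hash_of(config$test)
  )

  space <- config$space
  if (is.null(space)) {
    if (is.null(config$stack)) {
      stop("config needs either a stack or a prebuilt space", call. = FALSE)
    }
    space <- build_pca(config$stack, retention)
  }
  observed_occ <- if (is.null(config$observed_occ)) {
    rbind(
      calib[, c("longitude", "latitude", "population")],
      if (is.null(test)) NULL else test[, c("longitude", "latitude", "population")]
    )
  } else {
    load_occ(config$observed_occ, "observed")
  }
  ref <- models[[1]]
  oc_obs <- occurrence_cells(observed_occ, ref, what = "observed-niche")
  observed <- fit_mve(space_scores(space, unique(oc_obs$cell)))

  results <- list()
  binaries_0 <- list()
  for (i in seq_along(models)) {
    nm <- names(models)[i]
    mseed <- seed + 1000L * i
    entry <- tryCatch(
      {
        pred <- models[[i]]
        if (!grids_aligned(pred$geometry, ref$geometry)) {
          stop(sprintf("model '%s' is not aligned with the others", nm),
            call. = FALSE
          )
        }
        thresholds <- list()
        for (tol in omission) {
          bin <- threshold_by_omission(pred, calib, tol)
          gm <- if (is.null(test)) {
            list(status = "skipped: no evaluation occurrences")
          } else {
            or <- omission_rate(bin, test)
            ps <- proportion_suitable(bin)
            c(or, list(
              proportion_suitable = ps,
              cbp_p = cumulative_binomial(
                or$n_test - or$n_omitted, or$n_test, ps
              ),
              status = "ok"
            ))
          }
          key <- sprintf("tol_%g", tol)
          thresholds[[key]] <- c(
            list(threshold_value = bin$threshold_value),
            gm
          )
          if (tol == omission[1]) binaries_0[[nm]] <- bin
        }
        proc <- if (is.null(test)) {
          list(status = "skipped: no evaluation occurrences")
        } else {
          pr <- partial_roc(pred, test,
            E = proc_cfg$E,
            n_replicates = proc_cfg$n_replicates,
            resample_fraction = proc_cfg$resample_fraction,
            seed = mseed
          )
          c(unclass(pr), list(status = "ok"))
        }
        esp <- espace_report(binaries_0[[nm]], space, observed,
          jaccard_mode = jmode, mc_samples = mc, seed = mseed + 1L
        )
        aic_entry <- NULL
        acfg <- config$aic[[nm]]
        if (!is.null(acfg)) {
          lnL <- acfg$lnL
          if (is.null(lnL)) {
            lnL <- raster_log_likelihood(
              pred,
              rbind(calib, if (is.null(test)) NULL else test)
            )
          }
          aic_entry <- unclass(aic_result(acfg$K, lnL, acfg$n))
        }
        list(
          status = "ok", thresholds = thresholds, proc = proc,
          espace = unclass(esp), aic = aic_entry
        )
      },
      error = function(e) list(status = "error", message = conditionMessage(e))
    )
    results[[nm]] <- entry
  }

  ensemble <- NULL
  if (length(binaries_0) >= 2) {
    ens <- ensemble_sum(binaries_0)
    tab <- table(ens$values[is.finite(ens$values)])
    ensemble <- list(
      agreement_counts = as.list(stats::setNames(
        as.integer(tab), paste0("models_", names(tab))
      ))
    )
  }

  structure(
    list(
      config = list(
        seed = seed, omission = omission, proc = proc_cfg,
        jaccard_mode = jmode, mc_samples = mc,
        retention = space$retention,
        input_md5 = as.list(hashes)
      ),
      espace_summary = list(
        d = space$d,
        cumulative_explained = space$cumulative_explained,
        observed_volume = observed$volume,
        n_observed_cells = length(unique(oc_obs$cell))
      ),
      models = results, ensemble = ensemble
    ),
    class = "enm_evaluation"
  )
}

#' @export
print.enm_evaluation <- function(x, ...) {
  cat(sprintf(
    "enm_evaluation: %d models, seed %d, %d-dimensional E-space\n",
    length(x$models), x$config$seed, x$espace_summary$d
  ))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    if (m$status != "ok") {
      cat(sprintf("  %s: %s\n", nm, m$message))
      next
    }
    t0 <- m$thresholds[[1]]
    cat(sprintf(
      "  %-8s OR %s, area %s, interp %d, extrap %d, J %.3f\n", nm,
      if (is.null(t0$omission_rate)) "-" else sprintf("%.2f", t0$omission_rate),
      if (is.null(t0$proportion_suitable)) "-" else sprintf("%.2f", t0$proportion_suitable),
      m$espace$n_interpolation, m$espace$n_extrapolation, m$espace$jaccard
    ))
  }
  invisible(x)
}

#' Write an evaluation report to JSON (and optionally a CSV table)
#'
#' The JSON carries the full report; the CSV mirrors the geographic-space
#' table (one row per model and threshold: omission rate, proportional
#' suitable area, CBP p-value).
#'
#' @param report An [run_full_evaluation()] result.
#' @param json_path JSON output path.
#' @param csv_path Optional CSV output path.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  jsonlite::write_json(unclass(report), json_path,
    auto_unbox = TRUE,
    digits = NA, null = "null", force = TRUE
  )
  if (!is.null(csv_path)) {
    rows <- list()
    for (nm in names(report$models)) {
      m <- report$models[[nm]]
      if (m$status != "ok") next
      for (key in names(m$thresholds)) {
        t <- m$thresholds[[key]]
        rows[[length(rows) + 1]] <- data.frame(
          model = nm, tolerance = sub("tol_", "", key),
          threshold_value = t$threshold_value,
          omission_rate = if (is.null(t$omission_rate)) NA else t$omission_rate,
          proportion_suitable = if (is.null(t$proportion_suitable)) NA else t$proportion_suitable,
          cbp_p = if (is.null(t$cbp_p)) NA else t$cbp_p
        )
      }
    }
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
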