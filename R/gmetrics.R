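#' Threshold a continuous prediction by calibration omission tolerance
#'
#' Converts a continuous suitability surface to a binary map using the
#' omission-error thresholding rule: with calibration predictions sorted
#' `v[1] <= ... <= v[n]`, the threshold is the order statistic
#' `v[floor(tolerance * n) + 1]`. `tolerance = 0` gives the minimum
#' training presence (the smallest predicted value at any calibration
#' occurrence, i.e. 0% calibration omission); `tolerance = 0.05` discards
#' the 5% of calibration occurrences with the lowest predictions. Cells
#' with value `>= threshold` are suitable (closed at the threshold), so
#' the observed calibration omission never exceeds the tolerance.
#'
#' @param pred An [enm_raster()].
#' @param calib Calibration occurrence data frame.
#' @param omission_tolerance Fraction in `[0, 1)`.
#' @return An [enm_binary()] with threshold provenance recorded.
#' @export
threshold_by_omission <- function(pred, calib, omission_tolerance = 0) {
  stopifnot(
    inherits(pred, "enm_raster"),
    omission_tolerance >= 0, omission_tolerance < 1
  )
  oc <- occurrence_cells(calib, pred, what = "calibration")
  if (oc$n_usable == 0) {
    stop("no usable calibration occurrences on the prediction raster",
      call. = FALSE
    )
  }
  v <- sort(oc$value)
  thr <- v[floor(omission_tolerance * length(v)) + 1]
  suit <- pred$values >= thr
  suit[!is.finite(pred$values)] <- NA
  enm_binary(pred$geometry, suit,
    threshold_value = thr,
    omission_tolerance = omission_tolerance, source = "calibration"
  )
}

#' Omission rate of a binary map on test occurrences
#'
#' Fraction of usable evaluation occurrences that fall on cells predicted
#' unsuitable (the Type I error rate for presence-only evaluation).
#'
#' @param bin An [enm_binary()].
#' @param test Evaluation occurrence data frame.
#' @return List with `omission_rate`, `n_test` (usable records),
#'   `n_omitted`.
#' @export
omission_rate <- function(bin, test) {
  stopifnot(inherits(bin, "enm_binary"))
  r <- enm_raster(bin$geometry, ifelse(is.na(bin$suitable), NA_real_,
    as.numeric(bin$suitable)
  ))
  oc <- occurrence_cells(test, r, what = "evaluation")
  if (oc$n_usable == 0) {
    stop("no usable evaluation occurrences on the binary map", call. = FALSE)
  }
  n_omit <- sum(oc$value == 0)
  list(
    omission_rate = n_omit / oc$n_usable,
    n_test = oc$n_usable, n_omitted = n_omit
  )
}

#' Proportion of area predicted suitable
#'
#' Suitable cells divided by usable (non-nodata) cells, by plain cell
#' counting; an optional latitude-cosine weighting approximates true area
#' on wide-latitude grids.
#'
#' @param bin An [enm_binary()].
#' @param region_mask Optional logical matrix restricting the counted
#'   region (TRUE = counted).
#' @param latitude_weighted If TRUE, weight each cell by the cosine of its
#'   center latitude.
#' @return Fraction in `[0, 1]`.
#' @export
proportion_suitable <- function(bin, region_mask = NULL,
                                latitude_weighted = FALSE) {
  stopifnot(inherits(bin, "enm_binary"))
  s <- bin$suitable
  use <- !is.na(s)
  if (!is.null(region_mask)) use <- use & region_mask
  if (!any(use)) stop("region has no usable cells", call. = FALSE)
  if (latitude_weighted) {
    g <- bin$geometry
    top <- g$origin_lat + g$n_rows * g$cell_size
    lat <- top - (seq_len(g$n_rows) - 0.5) * g$cell_size
    w <- matrix(cos(lat * pi / 180), g$n_rows, g$n_cols)
    sum(w[use & s]) / sum(w[use])
  } else {
    sum(s[use]) / sum(use)
  }
}

#' One-tailed cumulative binomial probability
#'
#' `P(X >= n_success)` for `X ~ Binomial(n_trials, p_success)`: the
#' probability of predicting at least the observed number of evaluation
#' presences correctly if cells were hit at random with success
#' probability equal to the proportion of area predicted suitable. Small
#' values indicate better-than-random prediction.
#'
#' @param n_success,n_trials Non-negative counts, `n_success <= n_trials`.
#' @param p_success Success probability in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @examples
#' cumulative_binomial(7, 7, 0.5) # 0.5^7 = 0.0078125
#' @export
cumulative_binomial <- function(n_success, n_trials, p_success) {
  if (n_success < 0 || n_trials < 0 || n_success > n_trials ||
    n_success != round(n_success) || n_trials != round(n_trials)) {
    stop("invalid counts", call. = FALSE)
  }
  if (p_success < 0 || p_success > 1) {
    stop("p_success must be in [0, 1]", call. = FALSE)
  }
  if (n_success == 0) {
    return(1)
  }
  stats::pbinom(n_success - 1, n_trials, p_success, lower.tail = FALSE)
}

#' Bootstrap partial ROC for presence-only evaluation
#'
#' Assesses the relation between omission error on independent test
#' occurrences and the proportion of area predicted suitable, restricted
#' to the low-omission region (sensitivity `>= 1 - E`). Per bootstrap
#' replicate, `ceiling(resample_fraction * n)` of the `n` unique usable
#' test cells are drawn with replacement; the curve of (proportion of
#' area suitable, sensitivity) is swept over the prediction's value
#' classes; the partial AUC of the curve segment with sensitivity
#' `>= 1 - E` is divided by the partial AUC of the 1:1 null line over the
#' same segment. Ratios are bounded in `[0, 2]`: 1 is random performance,
#' values above 1 better than random. The replicate ratio is a rank
#' statistic: strictly increasing transforms of the prediction leave it
#' unchanged.
#'
#' @param pred An [enm_raster()] (non-constant over usable cells).
#' @param test Evaluation occurrence data frame (>= 2 usable cells).
#' @param E Omission-error tolerance in `(0, 0.5]` (default 0.05).
#' @param n_replicates Bootstrap replicates (default 100).
#' @param resample_fraction Fraction of test cells drawn per replicate
#'   (default 0.5).
#' @param seed Integer seed (mandatory; all randomness is local to the
#'   call).
#' @param max_classes Threshold sweep resolution: all distinct prediction
#'   values when there are at most this many, otherwise equal-quantile
#'   value classes (default 1000).
#' @return List of class `partial_roc` with `ratios`, `mean_ratio`,
#'   `p_value` (fraction of replicate ratios `<= 1`), `E`, `n_replicates`,
#'   `resample_fraction`, `n_test`, `seed`.
#' @export
partial_roc <- function(pred, test, E = 0.05, n_replicates = 100L,
                        resample_fraction = 0.5, seed,
                        max_classes = 1000L) {
  stopifnot(inherits(pred, "enm_raster"))
  if (E <= 0 || E > 0.5) stop("E must be in (0, 0.5]", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  vals <- pred$values[is.finite(pred$values)]
  if (length(unique(vals)) < 2) {
    stop("prediction is constant over usable cells", call. = FALSE)
  }
  oc <- occurrence_cells(test, pred, what = "evaluation")
  ucell <- unique(oc$cell)
  if (length(ucell) < 2) {
    stop("need at least 2 usable test occurrence cells", call. = FALSE)
  }
  test_vals <- oc$value[match(ucell, oc$cell)]
  thr <- sort(unique(vals))
  if (length(thr) > max_classes) {
    thr <- sort(unique(stats::quantile(vals,
      probs = seq(0, 1, length.out = max_classes),
      type = 1, names = FALSE
    )))
  }
  sv <- sort(vals)
  # area fraction suitable at each threshold (value >= threshold)
  area <- (length(sv) - findInterval(thr, sv, left.open = TRUE)) / length(sv)
  m <- ceiling(resample_fraction * length(ucell))
  band <- 1 - E
  one_ratio <- function(sample_vals) {
    ss <- sort(sample_vals)
    sens <- (m - findInterval(thr, ss, left.open = TRUE)) / m
    keep <- sens >= band
    if (sum(keep) < 2) {
      return(NA_real_)
    }
    x <- area[keep]
    y <- sens[keep]
    o <- order(x)
    x <- x[o]
    y <- y[o]
    dx <- diff(x)
    num <- sum(dx * (y[-1] + y[-length(y)]) / 2)
    den <- sum(dx * (x[-1] + x[-length(x)]) / 2)
    if (den <= 0) {
      return(NA_real_)
    }
    num / den
  }
  ratios <- withr::with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      one_ratio(test_vals[sample.int(length(test_vals), m, replace = TRUE)])
    }, numeric(1))
  })
  ok <- ratios[!is.na(ratios)]
  structure(
    list(
      ratios = ratios,
      mean_ratio = mean(ok),
      p_value = sum(ok <= 1) / length(ok),
      E = E, n_replicates = as.integer(n_replicates),
      resample_fraction = resample_fraction,
      n_test = length(ucell), seed = as.integer(seed)
    ),
    class = "partial_roc"
  )
}

#' @export
print.partial_roc <- function(x, ...) {
  cat(sprintf(
    "partial ROC: mean AUC ratio %.3f (E = %g, %d replicates of %g x %d test cells), p(ratio <= 1) = %.3f\n",
    x$mean_ratio, x$E, x$n_replicates, x$resample_fraction, x$n_test,
    x$p_value
  ))
  invisible(x)
}

#' Sum binary maps into an agreement ensemble
#'
#' Per-cell count of maps voting suitable; nodata wherever any input map
#' is nodata.
#'
#' @param maps List of at least two aligned [enm_binary()] maps.
#' @return An [enm_raster()] of integer agreement counts.
#' @export
ensemble_sum <- function(maps) {
  stopifnot(length(maps) >= 2)
  g <- maps[[1]]$geometry
  for (m in maps) {
    stopifnot(inherits(m, "enm_binary"))
    if (!grids_aligned(g, m$geometry)) {
      stop("binary maps are not aligned", call. = FALSE)
    }
  }
  acc <- matrix(0, g$n_rows, g$n_cols)
  nd <- matrix(FALSE, g$n_rows, g$n_cols)
  for (m in maps) {
    nd <- nd | is.na(m$suitable)
    acc <- acc + ifelse(is.na(m$suitable), 0, m$suitable)
  }
  acc[nd] <- NA_real_
  enm_raster(g, acc, name = "ensemble")
}
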