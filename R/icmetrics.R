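#' Akaike information criterion from a likelihood and parameter count
#'
#' `AIC = 2K - 2 ln(L)`.
#'
#' @param K Number of model parameters (>= 0).
#' @param lnL Maximized log-likelihood.
#' @return Numeric AIC.
#' @examples
#' aic(192, -1031.91) # 2447.82
#' @export
aic <- function(K, lnL) {
  stopifnot(K >= 0)
  2 * K - 2 * lnL
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2K(K + 1) / (n - K - 1)`, defined for `n > K + 1`; the
#' correction vanishes as `n` grows, and `AICc >= AIC` always.
#'
#' @param K Number of model parameters.
#' @param lnL Maximized log-likelihood.
#' @param n Sample size (number of occurrences).
#' @return Numeric AICc.
#' @export
aicc <- function(K, lnL, n) {
  stopifnot(K >= 0)
  if (n <= K + 1) {
    stop(sprintf(
      "AICc undefined: need n > K + 1 (n = %g, K = %g)", n, K
    ), call. = FALSE)
  }
  aic(K, lnL) + 2 * K * (K + 1) / (n - K - 1)
}

#' Parameter count for a quadratic no-interaction GLM
#'
#' One linear and one squared term per predictor, no interactions, the
#' intercept excluded from the count: `K = 2p`. With the first three
#' principal components as predictors, `K = 6`.
#'
#' @param p Number of predictors (>= 1).
#' @return Integer parameter count.
#' @export
glm_quadratic_K <- function(p) {
  stopifnot(p >= 1, p == round(p))
  as.integer(2 * p)
}

#' Parameter count for a classification model
#'
#' `K = N * (p + p(p + 1)/2 + c)` where `N` is the mean number of nodes
#' per regression tree (or individuals per genetic-algorithm population),
#' `p` the predictor dimensionality, and `c` the per-split penalty
#' (3 when each split separates records into true/false/unknown). `N` may
#' be a non-integer average; the product is rounded to the nearest
#' integer.
#'
#' @param N Mean nodes per tree / individuals per population (> 0).
#' @param p Predictor dimensionality (>= 1).
#' @param c Per-split penalty (>= 0).
#' @return Integer parameter count.
#' @examples
#' classification_K(16, 3, 3) # 192
#' classification_K(8, 3, 3) # 96
#' @export
classification_K <- function(N, p, c) {
  stopifnot(N > 0, p >= 1, p == round(p), c >= 0)
  as.integer(round(N * (p + p * (p + 1) / 2 + c)))
}

#' Occurrence log-likelihood of a continuous suitability raster
#'
#' Normalizes the prediction to a probability distribution over usable
#' cells (values divided by their total, so any positive rescaling of the
#' raster leaves the result unchanged) and sums the log normalized value
#' at each occurrence record. Records sharing a cell each contribute a
#' term (occurrence-level likelihood).
#'
#' @param pred An [enm_raster()] with non-negative values and positive
#'   total.
#' @param occ Occurrence data frame; every record must fall on a cell
#'   with positive predicted value.
#' @return The log-likelihood (a negative number for any non-trivial
#'   raster).
#' @export
raster_log_likelihood <- function(pred, occ) {
  stopifnot(inherits(pred, "enm_raster"))
  v <- pred$values[is.finite(pred$values)]
  if (any(v < 0) || sum(v) <= 0) {
    stop("prediction must be non-negative with positive total", call. = FALSE)
  }
  oc <- occurrence_cells(occ, pred, what = "occurrence")
  if (oc$n_usable < nrow(occ)) {
    stop("occurrence record(s) fall outside the raster or on nodata cells",
      call. = FALSE
    )
  }
  zero <- which(oc$value <= 0)
  if (length(zero) > 0) {
    stop(
      sprintf(
        "occurrence record(s) on zero-valued cells: %s",
        paste(zero, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  sum(log(oc$value / sum(v)))
}

#' Bundle AIC/AICc for a model
#'
#' @param K Parameter count.
#' @param lnL Maximized log-likelihood.
#' @param n Optional occurrence count; when given, AICc is included.
#' @return List of class `aic_result` with `K`, `lnL`, `n`, `aic`,
#'   `aicc` (`NA` when `n` is missing).
#' @export
aic_result <- function(K, lnL, n = NULL) {
  structure(
    list(
      K = K, lnL = lnL, n = if (is.null(n)) NA_integer_ else n,
      aic = aic(K, lnL),
      aicc = if (is.null(n)) NA_real_ else aicc(K, lnL, n)
    ),
    class = "aic_result"
  )
}

#' @export
print.aic_result <- function(x, ...) {
  cat(sprintf(
    "AIC = %.2f (K = %g, lnL = %.2f)%s\n", x$aic, x$K, x$lnL,
    if (is.na(x$aicc)) "" else sprintf(", AICc = %.2f (n = %d)", x$aicc, x$n)
  ))
  invisible(x)
}
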