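#' Environmental raster stack
#'
#' A named set of aligned environmental layers (e.g. bioclimatic
#' variables) on one grid. The common nodata mask is the union of the
#' layer masks.
#'
#' @param geometry A [grid_geometry()].
#' @param layers Named list of numeric matrices (`NA` = nodata), all
#'   matching the geometry; at least two layers.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(geometry, layers) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (length(layers) < 2) stop("an env_stack needs >= 2 layers", call. = FALSE)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- sprintf("env%02d", seq_along(layers))
  }
  for (nm in names(layers)) {
    m <- as.matrix(layers[[nm]])
    if (nrow(m) != geometry$n_rows || ncol(m) != geometry$n_cols) {
      stop(sprintf("layer '%s' does not match the grid geometry", nm),
        call. = FALSE
      )
    }
    layers[[nm]] <- m
  }
  structure(list(geometry = geometry, layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf(
    "env_stack: %d layers on a %d x %d grid (%s)\n",
    length(x$layers), x$geometry$n_rows, x$geometry$n_cols,
    paste(names(x$layers), collapse = ", ")
  ))
  invisible(x)
}

# Cells x layers matrix over the common (non-nodata) background, in
# row-major cell-id order.
stack_matrix <- function(stack) {
  cols <- lapply(stack$layers, function(m) as.vector(t(m)))
  X <- do.call(cbind, cols)
  colnames(X) <- names(stack$layers)
  ok <- rowSums(!is.finite(X)) == 0
  list(X = X[ok, , drop = FALSE], cell_ids = which(ok))
}

#' Build a principal-component environmental space
#'
#' Standardizes every layer to zero mean and unit variance over the
#' background (all non-nodata study-area cells), eigen-decomposes the
#' correlation structure, and retains the smallest leading set of
#' components whose cumulative explained variance reaches `retention`
#' (at least one component is always kept). Each loading column is
#' sign-flipped so its largest-magnitude entry is positive, making scores
#' reproducible across linear-algebra backends.
#'
#' @param stack An [env_stack()].
#' @param retention Cumulative explained-variance fraction to reach
#'   (default 0.90).
#' @return An object of class `env_space` with fields `cell_ids`, `scores`
#'   (background cells x retained components), `loadings`, `means`, `sds`,
#'   `explained` (all components), `cumulative_explained` (at the retained
#'   dimension), `d`, and the source `geometry`.
#' @export
build_pca <- function(stack, retention = 0.90) {
  stopifnot(inherits(stack, "env_stack"), retention >= 0, retention <= 1)
  sm <- stack_matrix(stack)
  X <- sm$X
  if (nrow(X) < ncol(X) + 1) {
    stop("too few non-nodata cells for a PCA", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      sprintf(
        "layer(s) with zero variance over the background: %s",
        paste(colnames(X)[sds == 0], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  explained <- pr$sdev^2 / sum(pr$sdev^2)
  d <- which(cumsum(explained) >= retention - 1e-12)[1]
  if (is.na(d)) d <- length(explained)
  d <- max(1L, d)
  load <- pr$rotation[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  Z <- scale(X, center = pr$center, scale = pr$scale)
  structure(
    list(
      cell_ids = sm$cell_ids,
      scores = unname(Z %*% load),
      loadings = load,
      means = pr$center, sds = pr$scale,
      explained = explained,
      cumulative_explained = cumsum(explained)[d],
      d = d, retention = retention,
      layer_names = colnames(X),
      geometry = stack$geometry
    ),
    class = "env_space"
  )
}

#' @export
print.env_space <- function(x, ...) {
  cat(sprintf(
    "env_space: %d background cells, %d of %d components retained (%.1f%% of variance)\n",
    length(x$cell_ids), x$d, length(x$explained),
    100 * x$cumulative_explained
  ))
  invisible(x)
}

#' Project raw environmental values into component space
#'
#' Applies the stored standardization and loadings:
#' `((raw - means) / sds) %*% loadings`.
#'
#' @param space An [build_pca()] result.
#' @param raw Numeric vector of length `n_layers`, or a matrix with one
#'   row per point.
#' @return Matrix of component scores (points x d).
#' @export
project_env <- function(space, raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  if (ncol(raw) != length(space$means)) {
    stop(
      sprintf(
        "expected %d layer values, got %d", length(space$means), ncol(raw)
      ),
      call. = FALSE
    )
  }
  z <- sweep(sweep(raw, 2, space$means), 2, space$sds, "/")
  unname(z %*% space$loadings)
}

# Component scores for given cell ids; NA rows for cells that are not
# part of the background (nodata).
space_scores <- function(space, cells) {
  idx <- match(cells, space$cell_ids)
  space$scores[idx, , drop = FALSE]
}

#' Serialize an environmental space to JSON (+ optional scores CSV)
#'
#' The JSON sidecar holds loadings, standardization constants and
#' explained-variance fractions; the (large) per-cell scores table can be
#' written to a separate CSV keyed by cell id.
#'
#' @param space An `env_space`.
#' @param path JSON output path.
#' @param scores_path Optional CSV output path for the scores table.
#' @export
write_env_space <- function(space, path, scores_path = NULL) {
  side <- list(
    loadings = unname(apply(space$loadings, 1, function(r) r, simplify = FALSE)),
    layer_names = space$layer_names,
    means = unname(space$means), sds = unname(space$sds),
    explained = space$explained,
    cumulative_explained = space$cumulative_explained,
    d = space$d, retention = space$retention,
    geometry = unclass(space$geometry)
  )
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(scores_path)) {
    df <- data.frame(cell = space$cell_ids)
    for (j in seq_len(space$d)) df[[sprintf("pc%d", j)]] <- space$scores[, j]
    utils::write.csv(df, scores_path, row.names = FALSE)
  }
  invisible(path)
}
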