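#' Unique environmental combinations of the suitable cells
#'
#' Projects all suitable, non-nodata cells of a binary map into the
#' retained component space and deduplicates identical environmental
#' combinations (after rounding to `digits` decimals in component units).
#'
#' @param bin An [enm_binary()] aligned with the space's source grid.
#' @param space An [build_pca()] environmental space.
#' @param digits Deduplication precision in component units (default 6).
#' @param region_mask Optional logical matrix restricting the cells
#'   considered.
#' @return Matrix of unique d-vectors (possibly 0 rows).
#' @export
unique_env_points <- function(bin, space, digits = 6, region_mask = NULL) {
  stopifnot(inherits(bin, "enm_binary"))
  if (!grids_aligned(bin$geometry, space$geometry)) {
    stop("binary map is not aligned with the environmental space grid",
      call. = FALSE
    )
  }
  suit <- bin$suitable
  if (!is.null(region_mask)) suit <- suit & region_mask
  cells <- which(as.vector(t(suit))) # row-major cell ids
  cells <- intersect(cells, space$cell_ids)
  if (length(cells) == 0) {
    return(matrix(numeric(0), ncol = space$d))
  }
  sc <- round(space_scores(space, cells), digits)
  sc[!duplicated(apply(sc, 1, paste, collapse = "\r")), , drop = FALSE]
}

#' E-space index I: interpolation and extrapolation frequencies
#'
#' Partitions the unique environmental combinations predicted suitable by
#' membership in the observed-niche ellipsoid: combinations inside are
#' interpolation (prediction within the observed environmental range),
#' combinations outside are extrapolation. The two counts always sum to
#' the number of unique suitable combinations.
#'
#' @param bin An [enm_binary()].
#' @param space An [build_pca()] environmental space.
#' @param observed The observed-niche [ellipsoid()] (the MVE of all
#'   available occurrences), of the same dimension as the space.
#' @param ... Passed to [unique_env_points()].
#' @return List with `n_interpolation`, `n_extrapolation`,
#'   `n_unique_suitable`.
#' @export
espace_index_I <- function(bin, space, observed, ...) {
  stopifnot(inherits(observed, "ellipsoid"))
  if (observed$d != space$d) {
    stop("observed ellipsoid dimension does not match the space", call. = FALSE)
  }
  pts <- unique_env_points(bin, space, ...)
  if (nrow(pts) == 0) {
    return(list(
      n_interpolation = 0L, n_extrapolation = 0L,
      n_unique_suitable = 0L
    ))
  }
  ins <- ellipsoid_contains(observed, pts)
  list(
    n_interpolation = sum(ins), n_extrapolation = sum(!ins),
    n_unique_suitable = nrow(pts)
  )
}

#' Jaccard similarity between two niche ellipsoids (Monte Carlo)
#'
#' `J = V(A intersect B) / (V(A) + V(B) - V(A intersect B))`. The
#' intersection volume is estimated by uniform Monte-Carlo sampling
#' inside the smaller-volume ellipsoid: the fraction of samples that also
#' fall in the other ellipsoid, times the smaller volume.
#'
#' @param a,b [ellipsoid()] objects of equal dimension; `a` may also be a
#'   point matrix, in which case its MVE is fit first.
#' @param mc_samples Monte-Carlo sample count (default 1e5).
#' @param seed Integer seed (randomness local to the call).
#' @return Fraction in `[0, 1]`.
#' @examples
#' b1 <- ellipsoid(c(0, 0, 0), diag(3))
#' b2 <- ellipsoid(c(0, 0, 0), diag(3) / 4)
#' jaccard_ellipsoid(b1, b2, mc_samples = 1e4, seed = 1) # ~ 1/8
#' @export
jaccard_ellipsoid <- function(a, b, mc_samples = 100000L, seed) {
  if (!inherits(a, "ellipsoid")) a <- fit_mve(a)
  stopifnot(inherits(b, "ellipsoid"), a$d == b$d)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (a$volume + b$volume <= 0) stop("zero-volume union", call. = FALSE)
  small <- if (a$volume <= b$volume) a else b
  big <- if (a$volume <= b$volume) b else a
  d <- small$d
  eg <- eigen(small$shape, symmetric = TRUE)
  # map of the unit ball onto `small`
  tr <- eg$vectors %*% diag(1 / sqrt(eg$values), d)
  frac <- withr::with_seed(seed, {
    g <- matrix(stats::rnorm(mc_samples * d), ncol = d)
    g <- g / sqrt(rowSums(g^2)) * stats::runif(mc_samples)^(1 / d)
    x <- sweep(g %*% t(tr), 2, small$center, "+")
    mean(ellipsoid_contains(big, x))
  })
  v_int <- frac * small$volume
  v_int / (a$volume + b$volume - v_int)
}

#' Jaccard similarity over discrete environmental combinations
#'
#' `J = |S intersect M| / |S union M|` where `S` is the set of unique
#' background combinations predicted suitable and `M` the set of unique
#' background combinations inside the observed-niche ellipsoid. Exact
#' (no sampling).
#'
#' @param bin An [enm_binary()].
#' @param space An [build_pca()] environmental space.
#' @param observed The observed-niche [ellipsoid()].
#' @param digits Deduplication precision (default 6).
#' @return Fraction in `[0, 1]`.
#' @export
jaccard_discrete <- function(bin, space, observed, digits = 6) {
  stopifnot(inherits(observed, "ellipsoid"))
  bg <- round(space$scores, digits)
  bg <- bg[!duplicated(apply(bg, 1, paste, collapse = "\r")), , drop = FALSE]
  s_in <- rep(FALSE, nrow(bg))
  suit_pts <- unique_env_points(bin, space, digits = digits)
  if (nrow(suit_pts) > 0) {
    key_bg <- apply(bg, 1, paste, collapse = "\r")
    key_s <- apply(suit_pts, 1, paste, collapse = "\r")
    s_in <- key_bg %in% key_s
  }
  m_in <- ellipsoid_contains(observed, bg)
  uni <- sum(s_in | m_in)
  if (uni == 0) stop("zero-volume union", call. = FALSE)
  sum(s_in & m_in) / uni
}

#' Degree of extrapolation: distance to the farthest outside prediction
#'
#' The Euclidean distance (in raw component units) between the
#' observed-niche centroid and the most distant unique suitable
#' combination lying outside the observed ellipsoid; 0 when no suitable
#' combination extrapolates.
#'
#' @param bin An [enm_binary()].
#' @param space An [build_pca()] environmental space.
#' @param observed The observed-niche [ellipsoid()].
#' @param ... Passed to [unique_env_points()].
#' @return Non-negative distance.
#' @export
extrapolation_distance <- function(bin, space, observed, ...) {
  pts <- unique_env_points(bin, space, ...)
  if (nrow(pts) == 0) {
    return(0)
  }
  out <- !ellipsoid_contains(observed, pts)
  if (!any(out)) {
    return(0)
  }
  dx <- sweep(pts[out, , drop = FALSE], 2, observed$center)
  sqrt(max(rowSums(dx^2)))
}

#' Full environmental-space evaluation report
#'
#' Bundles E-space index I (interpolation/extrapolation counts), the
#' Jaccard similarity between the modeled and observed niches (index II,
#' in the chosen mode), and the degree of extrapolation, with full
#' provenance. In `ellipsoid_volume` mode the modeled niche is the MVE
#' fit to the model's unique suitable combinations; when those are too
#' few or degenerate for an MVE, the Jaccard entry is `NA` with a
#' warning.
#'
#' @param bin An [enm_binary()].
#' @param space An [build_pca()] environmental space.
#' @param observed The observed-niche [ellipsoid()].
#' @param jaccard_mode `"ellipsoid_volume"` (default) or
#'   `"discrete_cells"`.
#' @param mc_samples Monte-Carlo samples for the ellipsoid mode.
#' @param seed Integer seed for the Monte-Carlo integral.
#' @param digits Deduplication precision (default 6).
#' @param region_mask Optional logical matrix restricting the analysis
#'   extent.
#' @return List of class `espace_report`.
#' @export
espace_report <- function(bin, space, observed,
                          jaccard_mode = c(
                            "ellipsoid_volume",
                            "discrete_cells"
                          ),
                          mc_samples = 100000L, seed = 1L, digits = 6,
                          region_mask = NULL) {
  jaccard_mode <- match.arg(jaccard_mode)
  idx <- espace_index_I(bin, space, observed,
    digits = digits,
    region_mask = region_mask
  )
  dist <- extrapolation_distance(bin, space, observed,
    digits = digits,
    region_mask = region_mask
  )
  jac <- NA_real_
  if (jaccard_mode == "discrete_cells") {
    jac <- jaccard_discrete(bin, space, observed, digits = digits)
  } else {
    pts <- unique_env_points(bin, space,
      digits = digits,
      region_mask = region_mask
    )
    fit <- tryCatch(fit_mve(pts), error = function(e) e)
    if (inherits(fit, "error")) {
      warning(
        paste(
          "modeled niche MVE could not be fit",
          sprintf("(%s); Jaccard reported as NA", conditionMessage(fit))
        ),
        call. = FALSE
      )
    } else {
      jac <- jaccard_ellipsoid(fit, observed,
        mc_samples = mc_samples,
        seed = seed
      )
    }
  }
  structure(
    list(
      n_interpolation = idx$n_interpolation,
      n_extrapolation = idx$n_extrapolation,
      n_unique_suitable = idx$n_unique_suitable,
      jaccard = jac, jaccard_mode = jaccard_mode,
      extrapolation_distance = dist,
      mc_samples = as.integer(mc_samples), seed = as.integer(seed)
    ),
    class = "espace_report"
  )
}

#' @export
print.espace_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "E-space report: %d interpolation + %d extrapolation of %d unique",
      " suitable combos\n  Jaccard %.3f (%s), extrapolation distance %.3f\n"
    ),
    x$n_interpolation, x$n_extrapolation, x$n_unique_suitable,
    x$jaccard, x$jaccard_mode, x$extrapolation_distance
  ))
  invisible(x)
}
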