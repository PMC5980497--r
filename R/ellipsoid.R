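#' Ellipsoid in component space
#'
#' Represents `{x : (x - center)' A (x - center) <= 1}` with `A` a
#' symmetric positive-definite shape matrix. The volume is
#' `V_d * det(A)^(-1/2)` where `V_d` is the unit-ball volume in `d`
#' dimensions (`V_2 = pi`, `V_3 = 4*pi/3`).
#'
#' @param center Numeric d-vector.
#' @param shape Symmetric positive-definite d x d matrix (symmetry checked
#'   to 1e-9; it is symmetrized before use).
#' @return An object of class `ellipsoid` with fields `center`, `shape`,
#'   `volume`, `d`.
#' @export
ellipsoid <- function(center, shape) {
  center <- as.numeric(center)
  shape <- as.matrix(shape)
  d <- length(center)
  stopifnot(nrow(shape) == d, ncol(shape) == d)
  if (max(abs(shape - t(shape))) > 1e-9 * max(1, max(abs(shape)))) {
    stop("shape matrix is not symmetric", call. = FALSE)
  }
  shape <- (shape + t(shape)) / 2
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("shape matrix is not positive definite", call. = FALSE)
  }
  structure(
    list(
      center = center, shape = shape,
      volume = unit_ball_volume(d) / sqrt(prod(ev)), d = d
    ),
    class = "ellipsoid"
  )
}

unit_ball_volume <- function(d) pi^(d / 2) / gamma(d / 2 + 1)

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf(
    "ellipsoid: d = %d, center (%s), volume %.6g\n",
    x$d, paste(sprintf("%.4g", x$center), collapse = ", "), x$volume
  ))
  invisible(x)
}

#' Volume of an ellipsoid
#'
#' @param e An [ellipsoid()].
#' @return `V_d * det(shape)^(-1/2)`.
#' @examples
#' ellipsoid_volume(ellipsoid(c(0, 0, 0), diag(3))) # 4*pi/3
#' @export
ellipsoid_volume <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  e$volume
}

#' Squared Mahalanobis-type membership distance
#'
#' `(x - center)' shape (x - center)`; points with value `<= 1` are inside
#' the ellipsoid.
#'
#' @param e An [ellipsoid()].
#' @param x Numeric d-vector or matrix with one point per row.
#' @return Numeric vector of non-negative distances.
#' @export
mahalanobis_sq <- function(e, x) {
  stopifnot(inherits(e, "ellipsoid"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != e$d) {
    stop(sprintf("points have dimension %d, ellipsoid %d", ncol(x), e$d),
      call. = FALSE
    )
  }
  dx <- sweep(x, 2, e$center)
  rowSums((dx %*% e$shape) * dx)
}

#' Ellipsoid membership test
#'
#' @param e An [ellipsoid()].
#' @param x Numeric d-vector or matrix with one point per row.
#' @param tol Boundary tolerance; membership is `mahalanobis_sq <= 1 + tol`.
#' @return Logical vector.
#' @export
ellipsoid_contains <- function(e, x, tol = 1e-9) {
  mahalanobis_sq(e, x) <= 1 + tol
}

#' Minimum-volume enclosing ellipsoid of a point set
#'
#' Fits the smallest-volume ellipsoid that encloses the points, by
#' Khachiyan's barycentric-coordinate-descent iteration. With
#' `coverage = 1` (the default) every input point is contained (membership
#' `<= 1 + 1e-9`; the shape is rescaled after convergence to guarantee
#' this) and the volume is within a factor `(1 + d * tolerance)` of the
#' true minimum. With `coverage = h < 1`, a robust variant encloses an
#' approximately minimal-volume `ceiling(h * n)`-point subset by greedy
#' outlier peeling: the point with the largest classical Mahalanobis
#' distance (location/scatter of the remaining subset) is dropped until
#' the subset size is reached, then the MVE of that subset is fit.
#'
#' @param points Matrix with one d-dimensional point per row; needs at
#'   least `d + 1` affinely independent points.
#' @param coverage Fraction of points to enclose, in `(0, 1]`.
#' @param tolerance Khachiyan convergence tolerance (default 1e-7).
#' @param max_iter Iteration cap (default 10000).
#' @return An [ellipsoid()].
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' fit_mve(sq)$volume # pi/2: the circumcircle of the unit square
#' @export
fit_mve <- function(points, coverage = 1, tolerance = 1e-7,
                    max_iter = 10000L) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  n <- nrow(P)
  d <- ncol(P)
  stopifnot(coverage > 0, coverage <= 1, tolerance > 0)
  if (n < d + 1) {
    stop(sprintf("need at least d + 1 = %d points, got %d", d + 1, n),
      call. = FALSE
    )
  }
  if (qr(cbind(P, 1))$rank < d + 1) {
    stop(paste(
      "point set is affinely dependent (rank-deficient);",
      "reduce the dimension before fitting an ellipsoid"
    ), call. = FALSE)
  }
  if (coverage < 1) {
    keep <- seq_len(n)
    h <- ceiling(coverage * n - 1e-9)
    if (h < d + 1) stop("coverage subset smaller than d + 1", call. = FALSE)
    while (length(keep) > h) {
      # peel by classical Mahalanobis distance (location/scatter of the
      # kept subset): on the MVE itself every support point is at
      # membership 1, so it cannot rank outliers
      Pk <- P[keep, , drop = FALSE]
      md <- stats::mahalanobis(Pk, colMeans(Pk), stats::cov(Pk))
      keep <- keep[-which.max(md)]
    }
    return(fit_mve(P[keep, , drop = FALSE],
      coverage = 1,
      tolerance = tolerance, max_iter = max_iter
    ))
  }
  # Khachiyan barycentric coordinate descent with Wolfe-Atwood away
  # ("drop") steps, which restore fast convergence near the optimum
  Q <- t(cbind(P, 1)) # (d+1) x n lifted points
  u <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    jp <- which.max(M)
    eps_plus <- M[jp] / (d + 1) - 1
    act <- which(u > 0)
    jm <- act[which.min(M[act])]
    eps_minus <- 1 - M[jm] / (d + 1)
    if (max(eps_plus, eps_minus) <= tolerance) break
    if (eps_plus >= eps_minus) {
      j <- jp
      step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    } else {
      j <- jm
      step <- max(
        (M[j] - d - 1) / ((d + 1) * (M[j] - 1)),
        -u[j] / (1 - u[j])
      )
    }
    u <- (1 - step) * u
    u[j] <- u[j] + step
    u[u < 0] <- 0
  }
  center <- drop(crossprod(P, u))
  S <- crossprod(P, u * P) - tcrossprod(center)
  A <- solve(S) / d
  A <- (A + t(A)) / 2
  # guarantee containment at the 1e-9 membership tolerance
  e <- ellipsoid(center, A)
  mmax <- max(mahalanobis_sq(e, P))
  if (mmax > 1) e <- ellipsoid(center, A / mmax)
  e
}

#' Serialize an ellipsoid to JSON
#'
#' @param e An [ellipsoid()].
#' @param path Output path.
#' @export
write_ellipsoid <- function(e, path) {
  jsonlite::write_json(
    list(
      center = e$center,
      shape = unname(apply(e$shape, 1, function(r) r, simplify = FALSE)),
      volume = e$volume, d = e$d
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an ellipsoid from JSON
#'
#' @param path JSON file written by [write_ellipsoid()].
#' @return An [ellipsoid()].
#' @export
read_ellipsoid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ellipsoid(j$center, matrix(unlist(j$shape), nrow = j$d, byrow = TRUE))
}
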