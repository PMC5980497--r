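make_stack <- function(layers, n = 10) {
  env_stack(small_geom(n), layers)
}

test_that("PCA of independent standardized layers spreads variance evenly", {
  withr::with_seed(11, {
    n <- 20
    layers <- list(
      a = matrix(rnorm(n^2), n, n),
      b = matrix(rnorm(n^2), n, n),
      c = matrix(rnorm(n^2), n, n)
    )
  })
  sp <- build_pca(make_stack(layers, 20), retention = 0.90)
  # each component explains ~1/3; all three needed to reach 90%
  expect_equal(sp$d, 3)
  expect_true(all(abs(sp$explained - 1 / 3) < 0.05))
  expect_true(sp$cumulative_explained >= 0.9999)
})

test_that("a duplicated layer collapses to one component", {
  withr::with_seed(12, x <- matrix(rnorm(100), 10, 10))
  sp <- build_pca(make_stack(list(a = x, b = 2 * x + 5)), retention = 0.90)
  expect_equal(sp$d, 1)
  expect_gt(sp$explained[1], 1 - 1e-12)
})

test_that("at least one component is always retained", {
  withr::with_seed(13, {
    layers <- list(a = matrix(rnorm(100), 10, 10), b = matrix(rnorm(100), 10, 10))
  })
  sp <- build_pca(make_stack(layers), retention = 0)
  expect_equal(sp$d, 1)
})

test_that("a constant layer raises a degenerate-variance error naming it", {
  layers <- list(a = matrix(1:100, 10, 10), flat = matrix(7, 10, 10))
  expect_error(build_pca(make_stack(layers)), "flat")
})

test_that("PCA satisfies its structural invariants", {
  st <- generate_env_stack(31, geometry = small_geom(15), n_layers = 5)
  sp <- build_pca(st, retention = 0.9)
  # explained fractions non-increasing and summing to 1
  expect_true(all(diff(sp$explained) <= 1e-12))
  expect_equal(sum(sp$explained), 1)
  # scores have zero column means over the background
  expect_true(all(abs(colMeans(sp$scores)) < 1e-10))
  # sign convention: largest-magnitude loading entry positive per column
  for (j in seq_len(sp$d)) {
    expect_gt(sp$loadings[which.max(abs(sp$loadings[, j])), j], 0)
  }
})

test_that("full-rank reconstruction reproduces the standardized data", {
  withr::with_seed(14, {
    layers <- list(
      a = matrix(rnorm(100), 10, 10), b = matrix(rnorm(100), 10, 10),
      c = matrix(rnorm(100), 10, 10)
    )
  })
  sp <- build_pca(make_stack(layers), retention = 1)
  X <- cbind(as.vector(t(layers$a)), as.vector(t(layers$b)), as.vector(t(layers$c)))
  Z <- scale(X)
  expect_lt(max(abs(sp$scores %*% t(sp$loadings) - Z)), 1e-8)
})

test_that("project_env is consistent, affine, and checks dimensions", {
  st <- generate_env_stack(32, geometry = small_geom(12), n_layers = 4)
  sp <- build_pca(st)
  # projecting the layer means gives the origin
  expect_true(all(abs(project_env(sp, sp$means)) < 1e-12))
  # projecting every background cell reproduces the scores
  X <- sapply(st$layers, function(m) as.vector(t(m)))
  expect_lt(max(abs(project_env(sp, X) - sp$scores)), 1e-10)
  # linearity
  a <- X[1, ]
  b <- X[2, ]
  resid <- project_env(sp, a) + project_env(sp, b) -
    2 * project_env(sp, (a + b) / 2)
  expect_lt(max(abs(resid)), 1e-10)
  expect_error(project_env(sp, c(1, 2)), "expected 4")
})

test_that("env_space serializes to JSON and scores CSV", {
  st <- generate_env_stack(33, geometry = small_geom(8), n_layers = 3)
  sp <- build_pca(st)
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_env_space(sp, fj, fc)
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$d, sp$d)
  expect_equal(j$means, unname(sp$means), tolerance = 1e-12)
  sc <- read.csv(fc)
  expect_equal(sc$cell, sp$cell_ids)
  expect_equal(sc$pc1, sp$scores[, 1], tolerance = 1e-12)
})

test_that("the minimum enclosing ellipse of the unit square is its circumcircle", {
  e <- fit_mve(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(e$center, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(e$volume, pi / 2, tolerance = 1e-4)
  expect_true(all(ellipsoid_contains(e, rbind(c(0, 0), c(1, 1)))))
})

test_that("MVE of points sampled on an ellipsoid surface recovers it", {
  # oracle: the generating ellipsoid itself
  gen <- ellipsoid(c(1, -2, 0.5), crossprod(matrix(
    c(1, 0.2, 0, 0, 0.5, 0.1, 0, 0, 2), 3, 3
  )))
  eg <- eigen(gen$shape, symmetric = TRUE)
  tr <- eg$vectors %*% diag(1 / sqrt(eg$values))
  withr::with_seed(21, {
    g <- matrix(rnorm(600), ncol = 3)
    g <- g / sqrt(rowSums(g^2)) # on the unit sphere
  })
  pts <- sweep(g %*% t(tr), 2, gen$center, "+")
  e <- fit_mve(pts)
  expect_true(all(ellipsoid_contains(e, pts)))
  expect_lte(e$volume, gen$volume * (1 + 1e-3))
  # and it can be no smaller than the generator either (points span it)
  expect_gte(e$volume, gen$volume * (1 - 1e-3))
})

test_that("d + 1 points in general position all lie on the MVE boundary", {
  tri <- rbind(c(0, 0), c(2, 0.3), c(0.7, 1.5))
  e <- fit_mve(tri)
  expect_true(all(abs(mahalanobis_sq(e, tri) - 1) < 1e-6))
})

test_that("MVE volume is monotone under point insertion", {
  withr::with_seed(22, {
    for (i in 1:25) {
      P <- matrix(rnorm(24), ncol = 2)
      v1 <- fit_mve(P)$volume
      v2 <- fit_mve(rbind(P, rnorm(2, sd = 2)))$volume
      expect_gte(v2, v1 * (1 - 1e-6))
    }
  })
})

test_that("MVE is affinely equivariant", {
  withr::with_seed(23, {
    P <- matrix(rnorm(60), ncol = 3)
    A <- matrix(rnorm(9), 3, 3) + diag(3) * 2
    b <- rnorm(3)
  })
  e1 <- fit_mve(P)
  e2 <- fit_mve(sweep(P %*% t(A), 2, b, "+"))
  expect_equal(e2$volume, e1$volume * abs(det(A)), tolerance = 1e-4)
  expect_equal(e2$center, drop(A %*% e1$center + b), tolerance = 1e-3)
})

test_that("degenerate point sets raise a rank-deficiency error", {
  line <- cbind(1:5, 2 * (1:5)) # collinear in 2-D
  expect_error(fit_mve(line), "rank-deficient")
  expect_error(fit_mve(matrix(rnorm(4), 2, 2)), "at least d \\+ 1")
})

test_that("robust coverage mode encloses the requested subset and ignores outliers", {
  withr::with_seed(24, P <- matrix(rnorm(100), ncol = 2))
  out <- rbind(P, c(50, 50))
  e_full <- fit_mve(out)
  e_rob <- fit_mve(out, coverage = 50 / 51)
  expect_lt(e_rob$volume, e_full$volume / 10)
  expect_true(all(ellipsoid_contains(e_rob, P)))
})

test_that("membership distance matches stats::mahalanobis and a Cholesky solve", {
  withr::with_seed(25, {
    P <- matrix(rnorm(40), ncol = 2)
    x <- matrix(rnorm(20), ncol = 2)
  })
  e <- fit_mve(P)
  direct <- mahalanobis_sq(e, x)
  # independent route 1: base stats::mahalanobis with cov = shape^{-1}
  expect_equal(direct,
    stats::mahalanobis(x, e$center, solve(e$shape)),
    tolerance = 1e-10
  )
  # independent route 2: Cholesky solve
  L <- chol(e$shape)
  dx <- sweep(x, 2, e$center)
  expect_equal(direct, rowSums((dx %*% t(L))^2), tolerance = 1e-10)
})

test_that("ellipsoid volume follows the closed form and scales homogeneously", {
  expect_equal(ellipsoid(c(0, 0, 0), diag(3))$volume, 4 * pi / 3,
    tolerance = 1e-12
  )
  e <- ellipsoid(c(0, 0, 0), diag(1 / c(1, 4, 9)))
  expect_equal(e$volume, 4 * pi / 3 * 1 * 2 * 3, tolerance = 1e-12)
  doubled <- ellipsoid(c(0, 0, 0), e$shape / 4) # all semi-axes x2
  expect_equal(doubled$volume, 8 * e$volume, tolerance = 1e-12)
  expect_error(ellipsoid(c(0, 0), matrix(c(1, 0, 0, -1), 2, 2)), "positive definite")
})

test_that("membership basics: center inside, far point outside, boundary within tolerance", {
  e <- ellipsoid(c(0, 0, 0), diag(3))
  expect_equal(mahalanobis_sq(e, c(0, 0, 0)), 0)
  expect_equal(mahalanobis_sq(e, c(2, 0, 0)), 4)
  expect_false(ellipsoid_contains(e, c(2, 0, 0)))
  expect_true(ellipsoid_contains(e, c(1, 0, 0) * (1 + 1e-12)))
  expect_error(mahalanobis_sq(e, c(1, 2)), "dimension")
})

test_that("ellipsoid JSON round trip preserves the fit", {
  withr::with_seed(26, e <- fit_mve(matrix(rnorm(30), ncol = 3)))
  f <- withr::local_tempfile(fileext = ".json")
  write_ellipsoid(e, f)
  back <- read_ellipsoid(f)
  expect_equal(back$center, e$center, tolerance = 1e-12)
  expect_equal(back$shape, e$shape, tolerance = 1e-12)
  expect_equal(back$volume, e$volume, tolerance = 1e-9)
})
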