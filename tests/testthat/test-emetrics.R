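test_that("unique environmental combinations are deduplicated", {
  sc <- cached_scenario(102)
  g <- sc$geometry
  # duplicate environments: a stack with few distinct values
  suit <- matrix(FALSE, g$n_rows, g$n_cols)
  suit[1, 1:2] <- TRUE
  bin <- enm_binary(g, suit)
  pts <- unique_env_points(bin, sc$space)
  expect_lte(nrow(pts), 2)
  # all-unsuitable map gives the empty set, not an error
  none <- enm_binary(g, matrix(FALSE, g$n_rows, g$n_cols))
  expect_equal(nrow(unique_env_points(none, sc$space)), 0)
  # identical environments collapse: binary map over a two-valued stack
  g2 <- small_geom(4)
  st2 <- env_stack(g2, list(
    a = matrix(rep(c(1, 2), each = 8), 4, 4),
    b = matrix(rep(c(3, 4), each = 8), 4, 4)
  ))
  sp2 <- build_pca(st2, retention = 1)
  all_suit <- enm_binary(g2, matrix(TRUE, 4, 4))
  expect_equal(nrow(unique_env_points(all_suit, sp2)), 2)
})

test_that("index I partitions unique suitable combinations by MVE membership", {
  sc <- cached_scenario(102)
  bin <- binarize(sc$pseudo_models$matched, 0.5)
  obs <- sc$observed_mve
  idx <- espace_index_I(bin, sc$space, obs)
  expect_identical(
    idx$n_interpolation + idx$n_extrapolation,
    idx$n_unique_suitable
  )
  # brute-force membership loop over the same point set
  pts <- unique_env_points(bin, sc$space)
  inside <- vapply(
    seq_len(nrow(pts)),
    function(i) mahalanobis_sq(obs, pts[i, ]) <= 1 + 1e-9, logical(1)
  )
  expect_equal(idx$n_interpolation, sum(inside))
  expect_equal(idx$n_extrapolation, sum(!inside))
  # empty suitable set -> (0, 0)
  none <- enm_binary(sc$geometry, matrix(FALSE, 60, 84))
  idx0 <- espace_index_I(none, sc$space, obs)
  expect_equal(idx0$n_interpolation + idx0$n_extrapolation, 0)
  # dimension mismatch is an error
  expect_error(
    espace_index_I(bin, sc$space, ellipsoid(c(0, 0), diag(2))),
    "dimension"
  )
})

test_that("ellipsoid-volume Jaccard matches nested/disjoint/identical oracles", {
  b1 <- ellipsoid(c(0, 0, 0), diag(3))
  b2 <- ellipsoid(c(0, 0, 0), diag(3) / 4) # radius 2
  # nested balls: V1/V2 = 1/8
  expect_equal(jaccard_ellipsoid(b1, b2, mc_samples = 1e5, seed = 5), 0.125,
    tolerance = 0.01
  )
  # symmetry within Monte-Carlo error
  expect_equal(
    jaccard_ellipsoid(b1, b2, mc_samples = 1e5, seed = 6),
    jaccard_ellipsoid(b2, b1, mc_samples = 1e5, seed = 7),
    tolerance = 0.01
  )
  # identical ellipsoids -> 1 (within MC tolerance)
  expect_equal(jaccard_ellipsoid(b1, b1, mc_samples = 1e5, seed = 8), 1,
    tolerance = 0.005
  )
  # far-apart ellipsoids -> 0 exactly
  far <- ellipsoid(c(100, 100, 100), diag(3))
  expect_equal(jaccard_ellipsoid(b1, far, mc_samples = 1e4, seed = 9), 0)
})

test_that("Monte-Carlo Jaccard error shrinks with sample size", {
  b1 <- ellipsoid(c(0, 0, 0), diag(3))
  b2 <- ellipsoid(c(1.2, 0, 0), diag(3) / 2.25) # partial overlap
  est <- function(n, seeds) {
    sapply(seeds, function(s) jaccard_ellipsoid(b1, b2, mc_samples = n, seed = s))
  }
  se_small <- sd(est(1000, 1:15))
  se_large <- sd(est(16000, 1:15))
  # a 16-fold sample increase should cut the spread about four-fold
  expect_lt(se_large, se_small / 2)
})

test_that("discrete-cells Jaccard is exact and agrees with the MC mode when dense", {
  sc <- cached_scenario(102)
  bin <- binarize(sc$pseudo_models$matched, 0.5)
  obs <- sc$observed_mve
  jd <- jaccard_discrete(bin, sc$space, obs)
  expect_gte(jd, 0)
  expect_lte(jd, 1)
  # self-similarity is exactly 1: suitable set = inside-observed set
  # membership on 6-decimal-rounded scores, matching the metric's
  # deduplication precision, so the suitable set IS the inside set
  bg <- round(sc$space$scores, 6)
  inside <- ellipsoid_contains(obs, bg)
  self_map <- matrix(FALSE, 60, 84)
  self_map[cbind(
    (sc$space$cell_ids[inside] - 1) %/% 84 + 1,
    (sc$space$cell_ids[inside] - 1) %% 84 + 1
  )] <- TRUE
  self_bin <- enm_binary(sc$geometry, self_map)
  expect_identical(jaccard_discrete(self_bin, sc$space, obs), 1)
  # when the suitable set densely fills its own MVE the two modes agree
  je <- jaccard_ellipsoid(fit_mve(unique_env_points(self_bin, sc$space)),
    obs,
    mc_samples = 1e5, seed = 10
  )
  expect_equal(je, jaccard_discrete(self_bin, sc$space, obs), tolerance = 0.05)
})

test_that("extrapolation distance is the max distance of outside suitable points", {
  sc <- cached_scenario(102)
  obs <- sc$observed_mve
  bin <- binarize(sc$pseudo_models$broad, 0.5)
  d <- extrapolation_distance(bin, sc$space, obs)
  # exhaustive loop oracle
  pts <- unique_env_points(bin, sc$space)
  out <- pts[!ellipsoid_contains(obs, pts), , drop = FALSE]
  brute <- if (nrow(out) == 0) 0 else {
    max(sqrt(rowSums(sweep(out, 2, obs$center)^2)))
  }
  expect_equal(d, brute, tolerance = 1e-12)
  # no outside points -> 0
  none <- enm_binary(sc$geometry, matrix(FALSE, 60, 84))
  expect_equal(extrapolation_distance(none, sc$space, obs), 0)
})

test_that("extrapolation distance is monotone under adding a farther cell", {
  sc <- cached_scenario(103)
  obs <- sc$observed_mve
  bin <- binarize(sc$pseudo_models$overfit, 0.5)
  d0 <- extrapolation_distance(bin, sc$space, obs)
  # add the background cell farthest from the observed centroid
  dists <- sqrt(rowSums(sweep(sc$space$scores, 2, obs$center)^2))
  far_cell <- sc$space$cell_ids[which.max(dists)]
  s2 <- bin$suitable
  s2[(far_cell - 1) %/% 84 + 1, (far_cell - 1) %% 84 + 1] <- TRUE
  d1 <- extrapolation_distance(enm_binary(sc$geometry, s2), sc$space, obs)
  expect_gte(d1, d0)
  # 6-decimal deduplication rounds the coordinates slightly
  expect_equal(d1, max(dists), tolerance = 1e-5)
})

test_that("espace_report bundles the indices with provenance and self-consistency", {
  sc <- cached_scenario(103)
  obs <- sc$observed_mve
  rep_b <- espace_report(binarize(sc$pseudo_models$broad, 0.5), sc$space, obs,
    mc_samples = 2e4, seed = 3
  )
  expect_identical(
    rep_b$n_interpolation + rep_b$n_extrapolation,
    rep_b$n_unique_suitable
  )
  expect_identical(rep_b$extrapolation_distance == 0, rep_b$n_extrapolation == 0L)
  expect_identical(rep_b$jaccard_mode, "ellipsoid_volume")
  expect_identical(rep_b$seed, 3L)
  rep_o <- espace_report(binarize(sc$pseudo_models$overfit, 0.5), sc$space, obs,
    mc_samples = 2e4, seed = 3
  )
  # overbroad model dominates the overfit model in both index-I coordinates
  expect_gt(rep_b$n_interpolation, rep_o$n_interpolation)
  expect_gt(rep_b$n_extrapolation, rep_o$n_extrapolation)
  # a pseudo-model that IS the observed niche: Jaccard ~ 1, extrapolation ~ 0
  inside <- ellipsoid_contains(obs, round(sc$space$scores, 6))
  m <- matrix(FALSE, 60, 84)
  m[cbind(
    (sc$space$cell_ids[inside] - 1) %/% 84 + 1,
    (sc$space$cell_ids[inside] - 1) %% 84 + 1
  )] <- TRUE
  rep_self <- espace_report(enm_binary(sc$geometry, m), sc$space, obs,
    jaccard_mode = "discrete_cells"
  )
  expect_identical(rep_self$jaccard, 1)
  expect_equal(rep_self$extrapolation_distance, 0)
})
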