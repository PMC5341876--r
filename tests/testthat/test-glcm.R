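test_that("checkerboard co-occurrence alternates at d=1 and matches at d=2", {
  q <- checkerboardQroi()
  g1 <- buildGlcm(q, c(1, 0, 0), 1)
  expect_equal(g1$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  g2 <- buildGlcm(q, c(1, 0, 0), 2)
  expect_equal(g2$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
})

test_that("GLCM equals a brute-force pair count on random inputs", {
  set.seed(202)
  dirs <- glcmDirections()
  for (rep in 1:25) {
    q <- randomQroi(sample(3:6, 3, replace = TRUE), sample(2:4, 1))
    dir <- dirs[sample(13, 1), ]
    d <- sample(1:3, 1)
    got <- buildGlcm(q, dir, d)
    want <- bruteGlcm(voxelData(q), dir * d)
    expect_identical(got$nPairs, want$nPairs)
    expect_equal(got$p, unname(want$p), tolerance = 1e-14)
  }
})

test_that("local features match hand-evaluated closed forms", {
  g <- buildGlcm(checkerboardQroi(), c(1, 0, 0), 1)
  f <- glcmFeatures(g)
  expect_equal(f[["energy"]], 0.5)
  expect_equal(f[["entropy"]], 1.0)
  expect_equal(f[["inertia"]], 1.0)
  expect_equal(f[["contrast"]], 1.0)
  expect_equal(f[["homogeneity"]], 0.5)
  expect_equal(f[["maximum_probability"]], 0.5)
  expect_equal(f[["cluster_tendency"]], 0.0)
  expect_equal(f[["cluster_shade"]], 0.0)
  expect_equal(f[["sum_mean"]], 3.0)
  expect_equal(f[["inverse_variance"]], 1.0)
  expect_equal(f[["correlation"]], -1.0)
})

test_that("single-level ROI degenerates to a diagonal point mass", {
  q <- qroiFromLevels(array(1L, c(3, 3, 3)), 2L)
  f <- glcmFeatures(buildGlcm(q, c(0, 0, 1), 1))
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["inertia"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_true(is.na(f[["correlation"]]))
})

test_that("features match an independent literal-formula evaluation", {
  set.seed(77)
  for (rep in 1:20) {
    q <- randomQroi(c(5, 5, 5), sample(2:5, 1))
    g <- buildGlcm(q, glcmDirections()[sample(13, 1), ], sample(1:3, 1))
    if (g$nPairs == 0L) next
    got <- glcmFeatures(g)
    want <- literalGlcmFeatures(g$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("matrices are symmetric with unit mass; inertia bounds contrast^2", {
  set.seed(88)
  for (rep in 1:15) {
    q <- randomQroi(c(5, 5, 4), 4)
    g <- buildGlcm(q, glcmDirections()[sample(13, 1), ], 1)
    if (g$nPairs == 0L) next
    expect_equal(g$p, t(g$p))
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    f <- glcmFeatures(g)
    expect_gte(f[["inertia"]], f[["contrast"]]^2 - 1e-12)
  }
})

test_that("level reversal preserves symmetric features and negates shade", {
  set.seed(55)
  q <- randomQroi(c(6, 6, 5), 5)
  lev <- voxelData(q)
  rev <- lev
  rev[lev != 0L] <- 6L - lev[lev != 0L]
  qr <- qroiFromLevels(rev, 5L)
  dir <- c(1, 1, 0)
  f <- glcmFeatures(buildGlcm(q, dir, 1))
  fr <- glcmFeatures(buildGlcm(qr, dir, 1))
  sym <- c("energy", "entropy", "inertia", "homogeneity",
           "maximum_probability")
  expect_equal(f[sym], fr[sym], tolerance = 1e-12)
  expect_equal(f[["cluster_shade"]], -fr[["cluster_shade"]],
               tolerance = 1e-12)
})

test_that("homogeneity is 1 exactly for diagonal matrices", {
  p <- diag(c(0.2, 0.3, 0.5))
  expect_equal(glcmFeatures(p)[["homogeneity"]], 1)
  p2 <- matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2)
  expect_lt(glcmFeatures((p2 + t(p2)) / 2)[["homogeneity"]], 1)
})

test_that("direction aggregation averages contributing directions only", {
  # isotropic constant ROI: all 13 directions identical
  q <- qroiFromLevels(array(1L, c(5, 5, 5)), 2L)
  agg <- aggregateGlcmFeatures(q, 1)
  one <- glcmFeatures(buildGlcm(q, c(1, 0, 0), 1))
  expect_equal(agg[names(one)], one, ignore_attr = TRUE)
  expect_identical(attr(agg, "nDirections"), 13L)

  # 2-voxel-thick slab: any direction with a z-component exits at d=3
  slab <- qroiFromLevels(array(sample(1:3, 6 * 6 * 2, replace = TRUE),
                               c(6, 6, 2)), 3L)
  agg3 <- aggregateGlcmFeatures(slab, 3)
  expect_identical(attr(agg3, "nDirections"),
                   sum(glcmDirections()[, "z"] == 0L))

  # aggregate equals the external mean of per-direction feature values
  set.seed(14)
  q2 <- randomQroi(c(6, 5, 6), 4)
  rows <- list()
  for (k in 1:13) {
    g <- buildGlcm(q2, glcmDirections()[k, ], 2)
    if (g$nPairs > 0L) rows[[length(rows) + 1L]] <- glcmFeatures(g)
  }
  expect_equal(aggregateGlcmFeatures(q2, 2),
               colMeans(do.call(rbind, rows)), ignore_attr = TRUE)
})

test_that("a pairless ROI raises a feature-set-missing error", {
  lev <- array(0L, c(5, 5, 5))
  lev[3, 3, 3] <- 1L
  q <- qroiFromLevels(lev, 2L)
  expect_identical(buildGlcm(q, c(1, 0, 0), 1)$nPairs, 0L)
  expect_error(aggregateGlcmFeatures(q, 1), "no direction")
})
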