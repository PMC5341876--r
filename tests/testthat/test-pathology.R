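test_that("valid compositions pass unchanged; off-grid ones are repaired", {
  c1 <- validateComposition(c(lepidic = 60, acinar = 40))
  expect_identical(unname(subtypePercent(c1)[c("lepidic", "acinar")]),
                   c(60, 40))
  c2 <- validateComposition(c(acinar = 47, papillary = 53))
  expect_identical(unname(subtypePercent(c2)[c("acinar", "papillary")]),
                   c(45, 55))
  # renormalization of a non-100 sum before gridding
  c3 <- validateComposition(c(lepidic = 30, acinar = 30))
  expect_identical(unname(subtypePercent(c3)[c("lepidic", "acinar")]),
                   c(50, 50))
  expect_identical(sum(subtypePercent(c3)), 100)
})

test_that("degenerate compositions are rejected", {
  expect_error(validateComposition(c()), "invalid composition")
  expect_error(validateComposition(c(lepidic = 0, solid = 0)), "sum to 0")
  expect_error(validateComposition(c(lepidic = -10, acinar = 110)),
               "non-negative")
  expect_error(validateComposition(c(oncocytic = 100)), "names")
})

test_that("fibrosis is stored outside the subtype simplex", {
  cc <- validateComposition(c(lepidic = 50, acinar = 50, fibrosis = 30))
  expect_identical(sum(subtypePercent(cc)), 100)
  expect_identical(fibrosisPercent(cc), 30)
})

test_that("heterogeneity index is the weighted mixture proportion", {
  expect_equal(heterogeneityIndex(validateComposition(c(lepidic = 100))), 0)
  expect_equal(heterogeneityIndex(validateComposition(c(lepidic = 50,
                                                        solid = 50))), 1)
  # oracle: plain dot product for random weights and compositions
  set.seed(404)
  for (rep in 1:25) {
    k <- sample(1:4, 1)
    comp <- sampleComposition(k)
    w <- stats::setNames(runif(5, 0, 3), RadHet:::SUBTYPES)
    expect_equal(heterogeneityIndex(comp, w),
                 sum(w * subtypePercent(comp) / 100))
  }
  expect_error(
    heterogeneityIndex(validateComposition(c(solid = 100)),
                       weights = c(lepidic = 1)),
    "missing weight")
})

test_that("index is insertion-order invariant and weight-monotone", {
  a <- validateComposition(c(acinar = 40, solid = 60))
  b <- validateComposition(c(solid = 60, acinar = 40))
  expect_equal(heterogeneityIndex(a), heterogeneityIndex(b))
  w1 <- defaultSubtypeWeights()
  w2 <- w1
  w2["solid"] <- w2["solid"] + 1
  expect_gt(heterogeneityIndex(a, w2), heterogeneityIndex(a, w1))
})

test_that("subtype count and group follow the three-level partition", {
  g1 <- subtypeCountAndGroup(validateComposition(c(acinar = 100)))
  expect_identical(g1$nSubtypes, 1L)
  expect_identical(as.character(g1$group), "ONE")
  g2 <- subtypeCountAndGroup(validateComposition(c(lepidic = 55,
                                                   acinar = 45)))
  expect_identical(as.character(g2$group), "TWO")
  g4 <- subtypeCountAndGroup(validateComposition(
    c(lepidic = 30, acinar = 40, papillary = 20, micropapillary = 10)))
  expect_identical(g4$nSubtypes, 4L)
  expect_identical(as.character(g4$group), "THREE_OR_FOUR")
})

test_that("the group partition is exhaustive and exclusive on the 5% grid", {
  set.seed(17)
  for (rep in 1:50) {
    comp <- sampleComposition(sample(1:4, 1))
    g <- subtypeCountAndGroup(comp)
    expect_identical(g$nSubtypes, sum(subtypePercent(comp) > 0))
    expected <- if (g$nSubtypes == 1L) "ONE" else if (g$nSubtypes == 2L)
      "TWO" else "THREE_OR_FOUR"
    expect_identical(as.character(g$group), expected)
    expect_false(is.na(g$group))
  }
})

test_that("predominance uses the aggressiveness tie-break", {
  expect_identical(predominantSubtype(validateComposition(
    c(lepidic = 20, acinar = 80))), "acinar")
  expect_identical(predominantSubtype(validateComposition(
    c(acinar = 50, solid = 50))), "solid")
  expect_identical(predominantSubtype(validateComposition(
    c(lepidic = 50, papillary = 50))), "papillary")
})
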