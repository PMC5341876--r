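test_that("sampled compositions live on the 5% simplex", {
  expect_identical(sum(subtypePercent(sampleComposition(1, seed = 3)) > 0),
                   1L)
  expect_identical(max(subtypePercent(sampleComposition(1, seed = 3))), 100)
  set.seed(111)
  for (rep in 1:100) {
    k <- sample(1:4, 1)
    p <- subtypePercent(sampleComposition(k))
    expect_identical(sum(p), 100)
    expect_true(all(p %% 5 == 0))
    expect_identical(sum(p > 0), as.integer(k))
  }
  expect_identical(subtypePercent(sampleComposition(3, seed = 9)),
                   subtypePercent(sampleComposition(3, seed = 9)))
})

test_that("a pure-solid noiseless phantom draws from its HU distribution", {
  spec <- phantomSpec(shape = c(32, 32, 26),
                      composition = validateComposition(c(solid = 100)),
                      noiseSd = 0, seed = 4)
  ph <- makePhantom(spec)
  roi <- extractRoi(ph$nonContrast, ph$mask)
  expect_gt(length(roiValues(roi)), 1e4)
  expect_lt(abs(mean(roiValues(roi)) - 30), 3)
  expect_lt(abs(sd(roiValues(roi)) - 60), 3)
  h <- computeHistogramFeatures(roi)
  expect_lt(abs(h[["skewness"]]), 0.1)
})

test_that("compartment volume fractions match the composition", {
  comp <- validateComposition(c(lepidic = 50, solid = 50))
  ph <- makePhantom(phantomSpec(composition = comp, seed = 12))
  tab <- table(ph$compartments[ph$compartments != 0])
  frac <- as.numeric(tab) / sum(tab)
  expect_true(all(abs(frac - 0.5) < 0.05))

  comp2 <- validateComposition(c(lepidic = 20, acinar = 45, solid = 35))
  ph2 <- makePhantom(phantomSpec(composition = comp2, seed = 13))
  tab2 <- table(ph2$compartments[ph2$compartments != 0])
  expect_true(all(abs(as.numeric(tab2) / sum(tab2) -
                        c(0.20, 0.45, 0.35)) < 0.05))
})

test_that("phantom generation is seed-deterministic and size-guarded", {
  comp <- validateComposition(c(lepidic = 50, acinar = 50))
  a <- makePhantom(phantomSpec(composition = comp, seed = 5))
  b <- makePhantom(phantomSpec(composition = comp, seed = 5))
  expect_identical(voxelData(a$nonContrast), voxelData(b$nonContrast))
  expect_identical(voxelData(a$iodine), voxelData(b$iodine))
  c2 <- makePhantom(phantomSpec(composition = comp, seed = 6))
  expect_false(identical(voxelData(a$nonContrast), voxelData(c2$nonContrast)))
  comp4 <- validateComposition(c(lepidic = 25, acinar = 25, papillary = 25,
                                 solid = 25))
  expect_error(makePhantom(phantomSpec(shape = c(5, 5, 5),
                                       composition = comp4)),
               "too small")
})

test_that("channels share geometry but differ in intensity scale", {
  comp <- validateComposition(c(acinar = 100))
  ph <- makePhantom(phantomSpec(composition = comp, seed = 31))
  nc <- mean(roiValues(extractRoi(ph$nonContrast, ph$mask)))
  io <- mean(roiValues(extractRoi(ph$iodine, ph$mask)))
  expect_lt(nc, -250)    # lung-window soft tissue
  expect_gt(io, 0)       # iodine uptake scale
})

test_that("a written cohort round-trips through the imaging module", {
  dirp <- file.path(tempdir(), "cohort1")
  co <- makeCohort(cohortSpec(1, seed = 77), outDir = dirp)
  expect_true(file.exists(file.path(dirp, "pathology.csv")))
  expect_true(file.exists(file.path(dirp, "manifest.json")))
  tab <- runExtraction(co$manifest, channels = "non_contrast")
  expect_identical(nrow(tab), 1L)
  expect_true(all(featureNames() %in% names(tab)))
  # ground truth in the manifest matches the pathology CSV
  path <- readPathologyTable(file.path(dirp, "pathology.csv"))
  comp <- validateComposition(unlist(path[1, RadHet:::SUBTYPES]))
  expect_equal(co$index[1], heterogeneityIndex(comp))
})

test_that("cohort mixture-size frequencies track the target distribution", {
  co <- makeCohort(cohortSpec(89, seed = 10))
  k <- table(factor(vapply(seq_len(89), function(i)
    sum(co$pathology[i, RadHet:::SUBTYPES] > 0), 1L), levels = 1:4))
  # Binomial(89, 0.607) has mean 54, sd 4.6: a 3-sigma band
  expect_gt(k[["2"]], 54 - 14)
  expect_lt(k[["2"]], 54 + 14)
  expect_identical(sum(k), 89L)
  co2 <- makeCohort(cohortSpec(89, seed = 11))
  expect_false(identical(co$pathology, co2$pathology))
})
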