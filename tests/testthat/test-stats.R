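test_that("Spearman is monotone-invariant with banded strength", {
  r <- spearmanCor(1:10, (1:10)^3)
  expect_equal(r$rho, 1)
  expect_identical(as.character(r$strength), "very_strong")
  expect_identical(as.character(strengthCategory(0.654)), "strong")
  expect_identical(as.character(strengthCategory(-0.654)), "strong")
  expect_identical(as.character(strengthCategory(0.19)), "very_weak")
  expect_identical(as.character(strengthCategory(0.45)), "moderate")
  expect_error(spearmanCor(rep(1, 5), 1:5), "constant")
})

test_that("small-sample Spearman p is the exhaustive permutation tail", {
  set.seed(606)
  x <- rnorm(6)
  y <- rnorm(6)
  expect_equal(spearmanCor(x, y)$p, oracleSpearmanP(x, y))
  # with ties
  x2 <- c(1, 1, 2, 3, 4, 4)
  y2 <- c(2, 1, 1, 3, 3, 4)
  expect_equal(spearmanCor(x2, y2)$p, oracleSpearmanP(x2, y2))
})

test_that("large-sample Spearman p uses the t approximation", {
  set.seed(19)
  x <- rnorm(30)
  y <- x + rnorm(30, 0, 2)
  r <- spearmanCor(x, y)
  tt <- r$rho * sqrt((30 - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tt), 28))
})

test_that("Pearson matches the textbook product-moment formula", {
  expect_equal(pearsonCor(1:10, 2 * (1:10) + 1)$rho, 1)
  expect_equal(pearsonCor(1:10, -(1:10))$rho, -1)
  x <- c(2.1, 3.4, 1.8, 5.0, 4.4, 2.2)
  y <- c(1.0, 2.9, 1.1, 4.8, 3.1, 2.5)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonCor(x, y)$rho, manual)
})

test_that("Spearman and Pearson invariances hold", {
  set.seed(21)
  x <- rnorm(25)
  y <- rnorm(25)
  expect_equal(spearmanCor(exp(x), y)$rho, spearmanCor(x, y)$rho)
  expect_equal(pearsonCor(3 * x + 2, y)$rho, pearsonCor(x, y)$rho)
})

test_that("Lin's concordance penalizes location shift", {
  x <- rnorm(40)
  expect_equal(linCcc(x, x), 1)
  x2 <- c(-5, 5)                       # population variance 25
  expect_equal(linCcc(x2, x2 + 10), 1 / 3)
  expect_equal(linCcc(rep(3, 5), rep(3, 5)), 1)
  expect_equal(linCcc(rep(3, 5), rep(4, 5)), 0)
  expect_equal(linCcc(rep(3, 5), 1:5), 0)
})

test_that("CCC is bounded by |Pearson| and equals it at matched moments", {
  set.seed(23)
  for (rep in 1:20) {
    x <- rnorm(30)
    y <- rnorm(30, 1, 2)
    expect_lte(abs(linCcc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  x <- rnorm(50)
  y <- rev(x)                          # same mean and variance
  expect_equal(linCcc(x, y), cor(x, y))
})

test_that("one-way ANOVA degenerates and reduces correctly", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anovaTukey(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  const <- list(a = rep(2, 3), b = rep(2, 4))
  resc <- anovaTukey(const)
  expect_equal(resc$F, 0)
  expect_equal(resc$p, 1)

  # k = 2: F equals the square of the pooled-variance t statistic
  set.seed(31)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  tt <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(anovaTukey(list(x = x, y = y))$F, unname(tt^2))
})

test_that("Tukey flags exactly the separated group", {
  set.seed(77)
  g <- list(g1 = rnorm(30), g2 = rnorm(30), g3 = rnorm(30, 5))
  res <- anovaTukey(g)
  expect_lt(res$p, 0.001)
  sig <- res$tukey$p_adj < 0.05
  names(sig) <- res$tukey$pair
  expect_false(sig[["g2-g1"]])
  expect_true(sig[["g3-g1"]])
  expect_true(sig[["g3-g2"]])
})

test_that("ANOVA F is invariant under a constant shift", {
  set.seed(41)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  gs <- lapply(g, `+`, 100)
  expect_equal(anovaTukey(g)$F, anovaTukey(gs)$F)
})

test_that("stepwise selection stops at a local AIC minimum", {
  set.seed(51)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 6), n,
                            dimnames = list(NULL, paste0("f", 1:6))))
  y <- 1.5 * X$f1 - X$f2 + rnorm(n, 0, 0.5)
  fit <- stepwiseAicFit(X, y)
  dat <- cbind(.y = y, X)
  base <- extractAIC(lm(reformulate(c("1", fit$selected), ".y"), dat))[2]
  for (f in names(X)) {
    terms <- if (f %in% fit$selected) setdiff(fit$selected, f)
             else c(fit$selected, f)
    nb <- extractAIC(lm(reformulate(c("1", terms), ".y"), dat))[2]
    expect_gte(nb, base - 1e-8)
  }
})

test_that("an uninformative candidate is not selected", {
  set.seed(52)
  X <- data.frame(f1 = rnorm(200))
  y <- rnorm(200)
  fit <- stepwiseAicFit(X, y)
  expect_length(fit$selected, 0)
  # and the AIC arithmetic agrees: adding it must not lower AIC
  dat <- data.frame(.y = y, X)
  expect_gte(extractAIC(lm(.y ~ f1, dat))[2],
             extractAIC(lm(.y ~ 1, dat))[2])
})

test_that("stepwise errors on insufficient data and drops NA rows", {
  expect_error(stepwiseAicFit(data.frame(a = c(1, 2)), c(1, 2)),
               "insufficient")
  X <- data.frame(a = c(1, 2, NA, 4, 5, 6, 7, 8))
  fit <- suppressWarnings(stepwiseAicFit(X, (1:8)^1.3 + c(0.2, -0.1)))
  expect_identical(fit$nDropped, 1L)
  expect_identical(fit$nUsed, 7L)
})

test_that("cross-validation is seeded, deterministic and sharp at no noise", {
  set.seed(61)
  n <- 80
  X <- as.data.frame(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, paste0("f", 1:5))))
  y <- 2 * X$f1 + X$f2 - X$f3          # noiseless: expect perfect-fit notes
  cv <- suppressWarnings(crossValidatedPrediction(X, y, k = 10, seed = 7))
  expect_gt(cv$cvPearson, 0.999)
  cv2 <- suppressWarnings(crossValidatedPrediction(X, y, k = 10, seed = 7))
  expect_identical(cv$foldId, cv2$foldId)
  expect_identical(cv$cvPearson, cv2$cvPearson)
  cv3 <- suppressWarnings(crossValidatedPrediction(X, y, k = 10, seed = 8))
  expect_false(identical(cv$foldId, cv3$foldId))
  expect_error(crossValidatedPrediction(X, y, k = 200, seed = 1), "folds")
  expect_error(crossValidatedPrediction(X, y, k = 10), "seed")
})
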