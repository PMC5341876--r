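STRENGTH_LEVELS <- c("very_weak", "weak", "moderate", "strong", "very_strong")

#' Correlation strength category
#'
#' Absolute-coefficient bands: [0, 0.20) very weak, [0.20, 0.40) weak,
#' [0.40, 0.60) moderate, [0.60, 0.80) strong, [0.80, 1] very strong.
#'
#' @param rho correlation coefficient in [-1, 1].
#' @return factor with the five strength levels.
#' @export
strengthCategory <- function(rho) {
  a <- abs(rho)
  idx <- findInterval(a, c(0, 0.2, 0.4, 0.6, 0.8), rightmost.closed = FALSE)
  factor(STRENGTH_LEVELS[idx], levels = STRENGTH_LEVELS)
}

# All permutations of 1..n as an n! x n matrix (row-wise).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with strength category
#'
#' rho is the Pearson correlation of average ranks (ties allowed). The
#' p-value is the exhaustive two-sided permutation tail probability for
#' n <= 9 (all n! rank permutations), and the t approximation
#' t = rho sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom for
#' n > 9.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return list with \code{rho}, \code{p}, \code{strength}, \code{n},
#'   \code{method} (class \code{radhetCorrelation}).
#' @export
spearmanCor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant input vector")
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- allPermutations(n)
    # rho is monotone in sum(rx * ry_perm) for fixed marginals, but ties make
    # the direct recomputation the safer exhaustive statistic
    rhos <- as.vector(stats::cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  structure(list(rho = rho, p = p, strength = strengthCategory(rho), n = n,
                 method = "spearman"),
            class = "radhetCorrelation")
}

#' Pearson product-moment correlation with strength category
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return list as in \code{\link{spearmanCor}}.
#' @export
pearsonCor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 strength = strengthCategory(ct$estimate), n = n,
                 method = "pearson"),
            class = "radhetCorrelation")
}

#' @export
print.radhetCorrelation <- function(x, ...) {
  cat(sprintf("%s correlation: rho = %.3f (%s), p = %.4g, n = %d\n",
              x$method, x$rho, as.character(x$strength), x$p, x$n))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' ccc = 2 cov(x, y) / (var x + var y + (mean x - mean y)^2) with population
#' (1/n) moments: agreement between two readings penalizing both correlation
#' loss and location/scale shift. Two identical constant vectors are in
#' perfect agreement (ccc 1); any other zero-variance pairing has ccc 0.
#'
#' @param x,y numeric vectors of equal length n >= 2.
#' @return numeric(1) in [-1, 1].
#' @examples
#' x <- c(-5, 5)           # population variance 25
#' linCcc(x, x + 10)        # 2*25 / (25 + 25 + 100) = 1/3
#' @export
linCcc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0)
    return(if (mx == my) 1 else 0)
  if (vx == 0 || vy == 0) return(0)
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' One-way ANOVA with Tukey HSD post-hoc comparison
#'
#' Fixed-effects one-way F test across k >= 2 groups (each n >= 2) with
#' Tukey honest-significant-difference pairwise p-values via the studentized
#' range distribution, using the Tukey-Kramer correction for unequal group
#' sizes (as implemented by \code{stats::TukeyHSD}). When all observations
#' are identical across groups the test degenerates to F = 0, p = 1.
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @return list with \code{groupStats} (mean, sd, n per group), \code{F},
#'   \code{p}, and \code{tukey} (data.frame of pairwise adjusted p-values).
#' @export
anovaTukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 observations")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  gs <- data.frame(group = names(groups),
                   n = vapply(groups, length, 1L),
                   mean = vapply(groups, mean, 1),
                   sd = vapply(groups, stats::sd, 1),
                   row.names = NULL)
  pairs <- utils::combn(names(groups), 2)
  pairNames <- paste(pairs[2, ], pairs[1, ], sep = "-")
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - mean(v))^2, 1))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  if (ssb <= .Machine$double.eps * sum(v^2 + 1) && ssw <= 0) {
    tuk <- data.frame(pair = pairNames, diff = 0, p_adj = 1)
    return(list(groupStats = gs, F = 0, p = 1, tukey = tuk))
  }
  fit <- stats::aov(v ~ g)
  an <- stats::anova(fit)
  Fv <- an[1, "F value"]
  pv <- an[1, "Pr(>F)"]
  if (!is.finite(Fv) && ssb <= .Machine$double.eps * sum(v^2 + 1)) {
    Fv <- 0
    pv <- 1
  }
  th <- stats::TukeyHSD(fit)$g
  tuk <- data.frame(pair = rownames(th), diff = th[, "diff"],
                    p_adj = th[, "p adj"], row.names = NULL)
  list(groupStats = gs, F = Fv, p = pv, tukey = tuk)
}

# Evaluate code with a private RNG state so package functions never disturb
# the caller's random stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bidirectional stepwise model selection by AIC
#'
#' Gaussian linear model selection starting from the intercept-only model:
#' at each step the single term addition or deletion with the lowest AIC is
#' taken, stopping at a local AIC minimum (so the final model's AIC is no
#' larger than that of any one-step neighbor). Deterministic given column
#' order; ties are resolved by \code{stats::step}'s stable ordering. Rows
#' with missing values are dropped (and their count reported).
#'
#' With \code{family = "binomial"} the continuous target is dichotomized at
#' its median and a logistic model is selected instead; the Gaussian path is
#' the primary analysis since model performance is judged by the Pearson
#' correlation of predictions with the continuous index.
#'
#' @param features data.frame (or matrix) of candidate predictors.
#' @param target numeric response vector (the heterogeneity index).
#' @param family \code{"gaussian"} (default) or \code{"binomial"}.
#' @return list of class \code{radhetModelFit} with \code{selected}
#'   (ordered character vector), \code{coefficients}, \code{aic},
#'   \code{model} (the fitted object), \code{nUsed}, \code{nDropped}.
#' @export
stepwiseAicFit <- function(features, target, family = c("gaussian",
                                                        "binomial")) {
  family <- match.arg(family)
  features <- as.data.frame(features)
  if (nrow(features) != length(target))
    stop("features and target must have the same number of rows")
  dat <- cbind(.y = target, features)
  ok <- stats::complete.cases(dat)
  nDropped <- sum(!ok)
  dat <- dat[ok, , drop = FALSE]
  if (nrow(dat) < 3L)
    stop("insufficient data: fewer than 3 complete rows")
  if (family == "binomial")
    dat$.y <- as.integer(dat$.y > stats::median(dat$.y))
  upper <- stats::reformulate(names(features), response = ".y")
  null <- if (family == "gaussian") stats::lm(.y ~ 1, data = dat)
          else stats::glm(.y ~ 1, data = dat, family = stats::binomial())
  fit <- stats::step(null, scope = list(lower = ~1, upper = upper),
                     direction = "both", trace = 0)
  structure(list(selected = attr(stats::terms(fit), "term.labels"),
                 coefficients = stats::coef(fit),
                 aic = stats::AIC(fit),
                 model = fit,
                 family = family,
                 nUsed = nrow(dat),
                 nDropped = nDropped),
            class = "radhetModelFit")
}

#' @export
print.radhetModelFit <- function(x, ...) {
  cat(sprintf("stepwise-AIC %s fit: %d term(s) selected (AIC %.2f, n = %d)\n",
              x$family, length(x$selected), x$aic, x$nUsed))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Ten-fold cross-validated prediction of the heterogeneity index
#'
#' Observations are shuffled under the given seed and split into k near-equal
#' folds; the full stepwise-AIC selection is re-run inside every training
#' split and out-of-fold predictions are assembled. Reported are the Pearson
#' correlation of out-of-fold predictions with the observed target (the
#' honest validation statistic) and, for comparison, the in-fold correlation
#' of the full-data model's fitted values.
#'
#' @param features data.frame of candidate predictors (complete rows only
#'   are used; rows with missing values are dropped).
#' @param target numeric response vector.
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for the fold assignment (mandatory).
#' @return list with \code{cvPredictions}, \code{cvPearson},
#'   \code{inFoldPearson}, \code{foldId}, \code{fit} (full-data fit),
#'   \code{k}, \code{seed}.
#' @export
crossValidatedPrediction <- function(features, target, k = 10L, seed) {
  if (missing(seed)) stop("a fold-assignment seed is required")
  features <- as.data.frame(features)
  ok <- stats::complete.cases(cbind(target, features))
  features <- features[ok, , drop = FALSE]
  target <- target[ok]
  n <- length(target)
  k <- as.integer(k)
  if (k > n) stop("cannot make ", k, " folds from ", n, " observations")
  foldId <- integer(n)
  withSeed(seed, foldId[sample.int(n)] <- rep_len(seq_len(k), n))
  preds <- numeric(n)
  for (f in seq_len(k)) {
    test <- foldId == f
    fit <- stepwiseAicFit(features[!test, , drop = FALSE], target[!test])
    preds[test] <- stats::predict(fit$model,
                                  newdata = features[test, , drop = FALSE])
  }
  fullFit <- stepwiseAicFit(features, target)
  cvR <- if (stats::sd(preds) == 0 || stats::sd(target) == 0) NA_real_
         else stats::cor(preds, target)
  fitted <- stats::fitted(fullFit$model)
  inR <- if (stats::sd(fitted) == 0 || stats::sd(target) == 0) NA_real_
         else stats::cor(fitted, target)
  list(cvPredictions = preds, cvPearson = cvR, inFoldPearson = inR,
       foldId = foldId, fit = fullFit, k = k, seed = seed)
}
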