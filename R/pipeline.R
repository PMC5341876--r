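#' Default pipeline configuration
#'
#' Collects every tunable of the extraction and analysis stages: the coarse
#' texture quantization (16 levels over a fixed [-1000, 400] HU window), the
#' fine histogram profile (256 bins over the same window) behind the regional
#' uniformity/entropy, the co-occurrence distances, zone connectivity,
#' subtype weights, fold count and seed. The configuration is serialized
#' into every report for provenance, and a re-run under an identical
#' configuration reproduces outputs byte for byte.
#'
#' @param ... named overrides of the defaults.
#' @return list of class \code{radhetConfig}.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    textureLevels = 16L,
    textureRange = c(-1000, 400),
    histBins = 256L,
    histRange = c(-1000, 400),
    distances = 1:3,
    connectivity = 26,
    size3d = FALSE,
    weights = defaultSubtypeWeights(),
    folds = 10L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "radhetConfig")
}

#' The frozen 51-feature schema
#'
#' 4 physical + 7 histogram + 4 regional + 12 local features at each of the
#' three voxel distances = 51 columns, in fixed report order (physical,
#' histogram, regional, local).
#'
#' @param distances co-occurrence distances (default 1:3).
#' @return character vector of feature names.
#' @export
featureNames <- function(distances = 1:3) {
  c("volume_cm3", "density", "mass_g", "size_mm",
    "skewness", "kurtosis", "hu_p2_5", "hu_p25", "hu_p50", "hu_p75",
    "hu_p97_5",
    "uniformity", "regional_entropy", "intensity_variability",
    "size_zone_variability",
    as.vector(t(outer(GLCM_FEATURE_NAMES, distances,
                      function(f, d) paste0(f, "_d", d)))))
}

#' Extract the full radiomic feature set of one tumor channel
#'
#' Computes all 51 features for a volume/mask pair. Features undefined on a
#' degenerate ROI (single voxel, zero variance, no valid voxel pairs) are
#' reported as NA rather than silently zeroed.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a co-registered \linkS4class{RoiMask}.
#' @param config a \code{\link{defaultRunConfig}} list.
#' @return named numeric(51) following \code{\link{featureNames}}.
#' @export
extractFeatures <- function(volume, mask, config = defaultRunConfig()) {
  roi <- extractRoi(volume, mask)
  out <- stats::setNames(rep(NA_real_, length(featureNames(config$distances))),
                         featureNames(config$distances))
  out[names(computePhysical(roi, size3d = config$size3d))] <-
    computePhysical(roi, size3d = config$size3d)
  out[names(computeHistogramFeatures(roi))] <- computeHistogramFeatures(roi)
  reg <- tryCatch({
    qroi <- quantizeRoi(volume, mask, config$textureLevels,
                        config$textureRange)
    glszm <- buildGlszm(qroi, config$connectivity)
    regionalFeatures(roi, glszm, config$histBins, config$histRange)
  }, error = function(e) NULL)
  if (!is.null(reg)) out[names(reg)] <- reg
  for (d in config$distances) {
    loc <- tryCatch(
      aggregateGlcmFeatures(quantizeRoi(volume, mask, config$textureLevels,
                                        config$textureRange), d),
      error = function(e) NULL)
    if (!is.null(loc))
      out[paste0(GLCM_FEATURE_NAMES, "_d", d)] <- loc
  }
  out
}

#' Run feature extraction over a cohort
#'
#' Accepts either an in-memory cohort from \code{\link{makeCohort}} or a
#' manifest data.frame with columns tumor_id, non_contrast, iodine (optional)
#' and mask holding file paths. Produces one row per tumor per channel with
#' the 51 feature columns. Per-row failures (unreadable files, degenerate
#' ROIs) are recorded in the \code{errors} attribute and the run continues;
#' if every row fails the run errors out.
#'
#' @param cohort cohort list or manifest data.frame.
#' @param config pipeline configuration.
#' @param channels channels to extract.
#' @return data.frame (tumor_id, channel, 51 features) of class
#'   \code{radhetCohortTable}, with attributes \code{config} and
#'   \code{errors}.
#' @export
runExtraction <- function(cohort, config = defaultRunConfig(),
                          channels = c("non_contrast", "iodine")) {
  channels <- match.arg(channels, several.ok = TRUE)
  getPair <- NULL
  if (is.data.frame(cohort)) {
    ids <- cohort$tumor_id
    getPair <- function(i, ch) {
      col <- if (ch == "non_contrast") "non_contrast" else "iodine"
      if (is.null(cohort[[col]])) stop("manifest lacks channel ", ch)
      list(volume = readVolume(cohort[[col]][i], channel = ch),
           mask = readMask(cohort$mask[i]))
    }
  } else if (is.list(cohort) && !is.null(cohort$phantoms)) {
    ids <- cohort$pathology$tumor_id
    getPair <- function(i, ch) {
      ph <- cohort$phantoms[[i]]
      list(volume = if (ch == "non_contrast") ph$nonContrast else ph$iodine,
           mask = ph$mask)
    }
  } else stop("cohort must be a manifest data.frame or a makeCohort() result")
  rows <- list()
  errors <- list()
  for (ch in channels) {
    for (i in seq_along(ids)) {
      feats <- tryCatch(
        {
          pair <- getPair(i, ch)
          extractFeatures(pair$volume, pair$mask, config)
        },
        error = function(e) e)
      if (inherits(feats, "error")) {
        errors[[length(errors) + 1L]] <- data.frame(
          tumor_id = ids[i], channel = ch,
          message = conditionMessage(feats))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          tumor_id = ids[i], channel = ch, t(feats),
          check.names = FALSE)
      }
    }
  }
  if (!length(rows))
    stop("feature extraction failed for every row of the cohort")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors) else NULL
  class(out) <- c("radhetCohortTable", class(out))
  out
}

# Merge a cohort feature table with pathology-derived quantities.
pathologyProfile <- function(pathology, weights = defaultSubtypeWeights()) {
  comps <- compositionsFromTable(pathology)
  data.frame(
    tumor_id = pathology$tumor_id,
    index = vapply(comps, heterogeneityIndex, 1, weights = weights),
    n_subtypes = vapply(comps, function(cc) subtypeCountAndGroup(cc)$nSubtypes,
                        1L),
    group = vapply(comps,
                   function(cc) as.character(subtypeCountAndGroup(cc)$group),
                   ""),
    predominant = vapply(comps, predominantSubtype, ""))
}

#' Correlation report of every feature against the heterogeneity index
#'
#' For each feature and channel: Spearman rho against the pathologic
#' heterogeneity index, its p-value and strength category. Rows follow the
#' frozen feature order (physical, histogram, regional, local). A constant
#' feature column yields a row with missing rho (recorded in the
#' \code{errors} attribute) rather than an error. No multiplicity
#' correction is applied; p-values are raw.
#'
#' @param cohort a \code{runExtraction} table.
#' @param pathology pathology data.frame (tumor_id + subtype percentages).
#' @param config pipeline configuration (for the subtype weights).
#' @return data.frame: feature, channel, rho, p, strength, n.
#' @export
runCorrelationTable <- function(cohort, pathology,
                                config = defaultRunConfig()) {
  prof <- pathologyProfile(pathology, config$weights)
  feats <- featureNames(config$distances)
  rows <- list()
  errors <- character()
  for (ch in intersect(VALID_CHANNELS, unique(cohort$channel))) {
    sub <- merge(cohort[cohort$channel == ch, , drop = FALSE], prof,
                 by = "tumor_id")
    for (f in feats) {
      x <- sub[[f]]
      ok <- !is.na(x) & !is.na(sub$index)
      res <- tryCatch(spearmanCor(x[ok], sub$index[ok]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("%s/%s: %s", ch, f,
                                    conditionMessage(res)))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, channel = ch, rho = NA_real_, p = NA_real_,
          strength = NA_character_, n = sum(ok))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, channel = ch, rho = res$rho, p = res$p,
          strength = as.character(res$strength), n = res$n)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "errors") <- if (length(errors)) errors else NULL
  out
}

#' Group-comparison report across subtype-count groups
#'
#' For each feature and channel: mean and SD within the ONE / TWO /
#' THREE_OR_FOUR subtype-count groups, the one-way ANOVA F and p, and Tukey
#' HSD pairwise adjusted p-values. All three groups must be non-empty with
#' at least 2 tumors each, otherwise the report errors naming the offending
#' group.
#'
#' @inheritParams runCorrelationTable
#' @return data.frame with per-group mean/sd/n columns, anova_F, anova_p and
#'   the three Tukey pairwise p columns.
#' @export
runGroupComparison <- function(cohort, pathology,
                               config = defaultRunConfig()) {
  prof <- pathologyProfile(pathology, config$weights)
  cnt <- table(factor(prof$group, levels = SUBTYPE_GROUPS))
  if (any(cnt < 2))
    stop("group(s) with fewer than 2 tumors: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  feats <- featureNames(config$distances)
  rows <- list()
  for (ch in intersect(VALID_CHANNELS, unique(cohort$channel))) {
    sub <- merge(cohort[cohort$channel == ch, , drop = FALSE], prof,
                 by = "tumor_id")
    for (f in feats) {
      ok <- !is.na(sub[[f]])
      groups <- split(sub[[f]][ok],
                      factor(sub$group[ok], levels = SUBTYPE_GROUPS))
      res <- tryCatch(anovaTukey(groups), error = function(e) NULL)
      row <- data.frame(feature = f, channel = ch)
      for (gname in SUBTYPE_GROUPS) {
        gv <- groups[[gname]]
        row[[paste0("mean_", gname)]] <- if (length(gv)) mean(gv) else NA
        row[[paste0("sd_", gname)]] <- if (length(gv) > 1) stats::sd(gv)
                                       else NA
        row[[paste0("n_", gname)]] <- length(gv)
      }
      row$anova_F <- if (is.null(res)) NA_real_ else res$F
      row$anova_p <- if (is.null(res)) NA_real_ else res$p
      if (!is.null(res)) {
        for (pi in seq_len(nrow(res$tukey)))
          row[[paste0("tukey_", gsub("-", "_vs_", res$tukey$pair[pi]))]] <-
            res$tukey$p_adj[pi]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Stepwise model selection and ten-fold cross-validated validation
#'
#' Fits the stepwise-AIC Gaussian model of the heterogeneity index on the
#' requested channel's features, then re-runs the full selection inside each
#' of k cross-validation folds. Both the in-fold Pearson r (fitted values of
#' the full-data model vs the index) and the honest out-of-fold r are
#' reported, together with the seed and selected features.
#'
#' @inheritParams runCorrelationTable
#' @param channel which channel's features enter the candidate set.
#' @return list with \code{fit}, \code{cv}, \code{inFoldPearson},
#'   \code{outOfFoldPearson}, \code{n}, \code{channel}, \code{config}.
#' @export
runModelValidation <- function(cohort, pathology, config = defaultRunConfig(),
                               channel = "non_contrast") {
  prof <- pathologyProfile(pathology, config$weights)
  sub <- merge(cohort[cohort$channel == channel, , drop = FALSE], prof,
               by = "tumor_id")
  feats <- featureNames(config$distances)
  X <- sub[, feats, drop = FALSE]
  X <- X[, vapply(X, function(col) sum(!is.na(col)) > 0 &&
                    stats::sd(col, na.rm = TRUE) > 0, TRUE), drop = FALSE]
  ok <- stats::complete.cases(X) & !is.na(sub$index)
  if (sum(ok) < 30L)
    stop("model validation needs at least 30 complete rows, got ", sum(ok))
  cv <- crossValidatedPrediction(X[ok, , drop = FALSE], sub$index[ok],
                                 k = config$folds, seed = config$seed)
  list(fit = cv$fit, cv = cv, inFoldPearson = cv$inFoldPearson,
       outOfFoldPearson = cv$cvPearson, n = sum(ok), channel = channel,
       config = config)
}

#' Dual-reader stability report (Lin's concordance)
#'
#' Given tumors with two independently drawn masks, extracts the feature set
#' under each mask and reports, per feature, Lin's concordance correlation
#' coefficient of the reader-A vs reader-B values across tumors, plus a
#' min / mean / SD summary and a per-feature reproducibility call at the
#' conventional 0.85 threshold. Tumors missing one of the masks are skipped
#' (recorded in \code{skipped}).
#'
#' @param pairs list of lists with elements \code{volume}, \code{maskA},
#'   \code{maskB} (ImageVolume / RoiMask objects).
#' @param config pipeline configuration.
#' @return list with \code{perFeature} (data.frame feature, ccc, stable),
#'   \code{summary} (min, mean, sd), \code{n}, \code{skipped}.
#' @export
runStability <- function(pairs, config = defaultRunConfig()) {
  a <- list()
  b <- list()
  skipped <- integer()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (is.null(p$maskA) || is.null(p$maskB) || is.null(p$volume)) {
      skipped <- c(skipped, i)
      next
    }
    a[[length(a) + 1L]] <- extractFeatures(p$volume, p$maskA, config)
    b[[length(b) + 1L]] <- extractFeatures(p$volume, p$maskB, config)
  }
  if (!length(a)) stop("no usable mask pairs")
  A <- do.call(rbind, a)
  B <- do.call(rbind, b)
  cccs <- vapply(colnames(A), function(f) {
    ok <- !is.na(A[, f]) & !is.na(B[, f])
    if (sum(ok) < 2L) return(NA_real_)
    linCcc(A[ok, f], B[ok, f])
  }, numeric(1))
  perFeature <- data.frame(feature = colnames(A), ccc = unname(cccs),
                           stable = unname(cccs) >= 0.85)
  ok <- !is.na(perFeature$ccc)
  summ <- if (any(ok))
    c(min = min(perFeature$ccc[ok]), mean = mean(perFeature$ccc[ok]),
      sd = stats::sd(perFeature$ccc[ok]))
  else c(min = NA_real_, mean = NA_real_, sd = NA_real_)
  list(perFeature = perFeature, summary = summ, n = nrow(A),
       skipped = skipped)
}

#' Cohort summary: exclusions, predominant subtypes, group frequencies
#'
#' Applies the exclusion flags (columns \code{benign}, \code{mucinous},
#' \code{insufficient_slides}; nonzero means excluded; absent columns mean
#' no exclusion), then tabulates the predominant subtype and subtype-count
#' group of the surviving tumors with percentages rounded to one decimal.
#'
#' @param pathology pathology data.frame or CSV path.
#' @return list with \code{nTotal}, \code{nExcluded} (named by reason),
#'   \code{nIncluded}, \code{predominant} (data.frame subtype, n, pct),
#'   \code{groups} (data.frame group, n, pct).
#' @export
summarizeCohort <- function(pathology) {
  df <- if (is.character(pathology)) readPathologyTable(pathology)
        else pathology
  flags <- intersect(c("benign", "mucinous", "insufficient_slides"),
                     names(df))
  excl <- stats::setNames(integer(length(flags)), flags)
  keep <- rep(TRUE, nrow(df))
  for (fl in flags) {
    hit <- !is.na(df[[fl]]) & df[[fl]] != 0
    excl[fl] <- sum(hit & keep)
    keep <- keep & !hit
  }
  inc <- df[keep, , drop = FALSE]
  comps <- compositionsFromTable(inc)
  pred <- factor(vapply(comps, predominantSubtype, ""), levels = SUBTYPES)
  grp <- factor(vapply(comps,
                       function(cc) as.character(subtypeCountAndGroup(cc)$group),
                       ""), levels = SUBTYPE_GROUPS)
  tab <- function(f) {
    t <- table(f)
    data.frame(level = names(t), n = as.integer(t),
               pct = round(100 * as.integer(t) / length(f), 1))
  }
  list(nTotal = nrow(df), nExcluded = excl, nIncluded = nrow(inc),
       predominant = tab(pred), groups = tab(grp))
}

#' Transcribed reference cohort table
#'
#' A 93-lesion pathology table whose surviving 89 tumors reproduce the
#' clinicopathologic characteristics of a published prospective cohort of
#' resected stage I-II lung adenocarcinomas: 19 single-subtype, 54
#' two-subtype, 14 three-subtype and 2 four-subtype tumors with predominant
#' counts lepidic 18, acinar 53, papillary 11, micropapillary 6, solid 1,
#' plus 4 excluded lesions (1 benign, 1 mucinous, 2 with insufficient
#' slides). Compositions are representative splits consistent with the
#' published combination and predominance counts, not per-tumor data (which
#' are not deposited).
#'
#' @return data.frame usable with \code{\link{summarizeCohort}}.
#' @export
referenceCohort <- function() {
  rows <- list()
  add <- function(n, comp) {
    for (i in seq_len(n)) rows[[length(rows) + 1L]] <<- comp
  }
  # single-subtype tumors: 5 lepidic, 11 acinar, 3 papillary
  add(5, c(lepidic = 100))
  add(11, c(acinar = 100))
  add(3, c(papillary = 100))
  # two-subtype: lepidic+acinar 31 (13 lepidic-, 18 acinar-predominant)
  add(13, c(lepidic = 60, acinar = 40))
  add(18, c(lepidic = 40, acinar = 60))
  # acinar+papillary 13 (5 acinar-, 8 papillary-predominant)
  add(5, c(acinar = 60, papillary = 40))
  add(8, c(acinar = 40, papillary = 60))
  # acinar+micropapillary 1 (micropapillary-predominant)
  add(1, c(acinar = 40, micropapillary = 60))
  # acinar+solid 9 (8 acinar-, 1 solid-predominant)
  add(8, c(acinar = 60, solid = 40))
  add(1, c(acinar = 40, solid = 60))
  # three-subtype: 6 lepidic+acinar+papillary, 2 lepidic+acinar+solid
  # (acinar-predominant)
  add(6, c(lepidic = 30, acinar = 50, papillary = 20))
  add(2, c(lepidic = 30, acinar = 50, solid = 20))
  # acinar+papillary+micropapillary 4 (micropapillary-predominant)
  add(4, c(acinar = 30, papillary = 20, micropapillary = 50))
  # acinar+micropapillary+solid 2 (1 micropapillary-, 1 acinar-predominant)
  add(1, c(acinar = 30, micropapillary = 50, solid = 20))
  add(1, c(acinar = 50, micropapillary = 30, solid = 20))
  # four-subtype: 2 acinar-predominant
  add(2, c(lepidic = 20, acinar = 40, papillary = 25, micropapillary = 15))
  full <- stats::setNames(rep(0, 5), SUBTYPES)
  df <- do.call(rbind, lapply(rows, function(r) {
    p <- full
    p[names(r)] <- r
    as.data.frame(as.list(p))
  }))
  df <- cbind(tumor_id = sprintf("P%03d", seq_len(nrow(df))), df,
              benign = 0, mucinous = 0, insufficient_slides = 0)
  # the 4 excluded lesions of the screening flow
  excl <- data.frame(tumor_id = c("X001", "X002", "X003", "X004"),
                     lepidic = 0, acinar = c(0, 100, 100, 100),
                     papillary = 0, micropapillary = 0, solid = 0,
                     benign = c(1, 0, 0, 0), mucinous = c(0, 1, 0, 0),
                     insufficient_slides = c(0, 0, 1, 1))
  out <- rbind(df, excl)
  rownames(out) <- NULL
  out
}
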