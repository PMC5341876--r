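# Default HU emission distributions per growth pattern, ordered along the
# radiologic ground-glass -> solid spectrum. These are package defaults for
# phantom generation (configurable), not measurements: only their ordering
# is relied on by the directionality checks.
DEFAULT_SUBTYPE_HU <- list(
  lepidic        = c(mean = -650, sd = 80),
  acinar         = c(mean = -300, sd = 90),
  papillary      = c(mean = -150, sd = 90),
  micropapillary = c(mean =  -50, sd = 80),
  solid          = c(mean =   30, sd = 60))

# Iodine-map analogue: uptake ordered by expected vascularity of the
# pattern, on the iodine-image HU scale.
DEFAULT_SUBTYPE_IODINE <- list(
  lepidic        = c(mean = 10, sd = 15),
  acinar         = c(mean = 35, sd = 20),
  papillary      = c(mean = 50, sd = 20),
  micropapillary = c(mean = 65, sd = 20),
  solid          = c(mean = 80, sd = 20))

# Subtype-combination frequencies by mixture size, from the characteristic
# table of a published 89-tumor stage I-II lung adenocarcinoma cohort; used
# to weight which patterns co-occur in sampled compositions.
COMBINATION_WEIGHTS <- list(
  `1` = list(list(c("lepidic"), 5), list(c("acinar"), 11),
             list(c("papillary"), 3)),
  `2` = list(list(c("lepidic", "acinar"), 31),
             list(c("acinar", "papillary"), 13),
             list(c("acinar", "micropapillary"), 1),
             list(c("acinar", "solid"), 9)),
  `3` = list(list(c("lepidic", "acinar", "papillary"), 6),
             list(c("lepidic", "acinar", "solid"), 2),
             list(c("acinar", "papillary", "micropapillary"), 4),
             list(c("acinar", "micropapillary", "solid"), 2)),
  `4` = list(list(c("lepidic", "acinar", "papillary", "micropapillary"), 2)))

# Cohort distribution over mixture sizes 1..4 (counts 19/54/14/2 of 89).
DEFAULT_SUBTYPE_COUNT_PROBS <- c(`1` = 19, `2` = 54, `3` = 14, `4` = 2) / 89

#' Sample a ground-truth subtype composition
#'
#' Chooses k distinct growth patterns (weighted toward the combinations
#' frequent in resected stage I-II adenocarcinoma cohorts), draws their
#' proportions from a flat Dirichlet, and rounds onto the 5\% grid by
#' largest-remainder allocation with every chosen subtype kept strictly
#' positive.
#'
#' @param k number of subtypes (1-4).
#' @param seed optional RNG seed; when NULL the current RNG stream is used.
#' @return a \linkS4class{SubtypeComposition}.
#' @export
sampleComposition <- function(k, seed = NULL) {
  k <- as.integer(k)
  if (!k %in% 1:4) stop("k must be 1, 2, 3 or 4")
  draw <- function() {
    combos <- COMBINATION_WEIGHTS[[as.character(k)]]
    wts <- vapply(combos, function(cc) cc[[2]], 1)
    subs <- combos[[sample.int(length(combos), 1L, prob = wts)]][[1]]
    prop <- stats::rgamma(k, shape = 1)
    prop <- prop / sum(prop)
    units <- prop * 20
    fl <- pmax(floor(units), 1)            # every chosen subtype > 0
    while (sum(fl) > 20) {                 # pay for the floors from the top
      j <- which.max(fl)
      fl[j] <- fl[j] - 1
    }
    rem <- units - fl
    short <- 20L - as.integer(sum(fl))
    if (short > 0L) {
      ord <- order(-rem)
      fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
    }
    p <- stats::setNames(numeric(5), SUBTYPES)
    p[subs] <- fl * 5
    new("SubtypeComposition", percent = p, fibrosis = NA_real_)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Specification of one synthetic dual-energy tumor phantom
#'
#' @param shape integer(3) grid dimensions.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param composition a \linkS4class{SubtypeComposition} (ground truth).
#' @param subtypeHu named list of c(mean, sd) HU emission parameters for the
#'   non-contrast channel.
#' @param subtypeIodine same for the iodine channel.
#' @param noiseSd additive global Gaussian HU noise (default 20, a typical
#'   soft-reconstruction CT noise level).
#' @param seed integer RNG seed.
#' @return list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(shape = c(28, 28, 22), spacing = c(1, 1, 1),
                        composition, subtypeHu = DEFAULT_SUBTYPE_HU,
                        subtypeIodine = DEFAULT_SUBTYPE_IODINE,
                        noiseSd = 20, seed = 1L) {
  stopifnot(is(composition, "SubtypeComposition"), length(shape) == 3L,
            all(shape >= 5), noiseSd >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 composition = composition, subtypeHu = subtypeHu,
                 subtypeIodine = subtypeIodine, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

#' Generate one dual-energy tumor phantom
#'
#' Builds an ellipsoidal tumor mask filling the grid, partitions it into
#' spatial compartments whose volume fractions match the ground-truth
#' composition (seeded interior points with quota-constrained
#' nearest-seed assignment, giving contiguous irregular regions resembling
#' growth-pattern territories; realized fractions are within 5 percentage
#' points of the composition by construction), draws each compartment's
#' voxels from its subtype's HU distribution, and adds global Gaussian
#' noise. The iodine channel shares the spatial partition with its own
#' emission parameters.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{nonContrast} and \code{iodine}
#'   (\linkS4class{ImageVolume}s), \code{mask} (\linkS4class{RoiMask}),
#'   \code{composition}, \code{compartments} (integer array of compartment
#'   ids), and \code{index} (ground-truth heterogeneity index under the
#'   default weights).
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  d <- spec$shape
  ctr <- (d + 1) / 2
  radii <- (d - 2) / 2
  xs <- ((seq_len(d[1]) - ctr[1]) / radii[1])^2
  ys <- ((seq_len(d[2]) - ctr[2]) / radii[2])^2
  zs <- ((seq_len(d[3]) - ctr[3]) / radii[3])^2
  mask <- outer(outer(xs, ys, `+`), zs, `+`) <= 1
  idx <- which(mask)
  N <- length(idx)
  pos <- subtypePercent(spec$composition)
  subs <- names(pos)[pos > 0]
  k <- length(subs)
  if (N < 10L * k)
    stop("phantom mask too small to host ", k, " compartments (",
         N, " voxels)")
  frac <- pos[subs] / 100

  withSeed(spec$seed, {
    coords <- arrayInd(idx, d)
    seedPts <- coords[sample.int(N, k), , drop = FALSE]
    # quota-constrained nearest-seed assignment
    quota <- floor(frac * N)
    rem <- frac * N - quota
    for (j in order(-rem)[seq_len(N - sum(quota))])
      quota[j] <- quota[j] + 1
    dists <- vapply(seq_len(k), function(s)
      sqrt(rowSums(sweep(coords, 2, seedPts[s, ], `-`)^2)), numeric(N))
    assign <- integer(N)
    left <- quota
    ordPairs <- order(dists)               # over the N*k distance matrix
    for (o in ordPairs) {
      vox <- (o - 1L) %% N + 1L
      cmp <- (o - 1L) %/% N + 1L
      if (assign[vox] == 0L && left[cmp] > 0L) {
        assign[vox] <- cmp
        left[cmp] <- left[cmp] - 1L
      }
    }
    comp <- array(0L, dim = d)
    comp[idx] <- assign

    emit <- function(pars) {
      v <- array(-1000, dim = d)           # air background
      for (s in seq_len(k)) {
        sel <- idx[assign == s]
        mu <- pars[[subs[s]]][["mean"]]
        sd <- pars[[subs[s]]][["sd"]]
        v[sel] <- stats::rnorm(length(sel), mu, sd)
      }
      if (spec$noiseSd > 0)
        v[idx] <- v[idx] + stats::rnorm(N, 0, spec$noiseSd)
      v
    }
    nc <- emit(spec$subtypeHu)
    io <- emit(spec$subtypeIodine)
  })

  list(nonContrast = ImageVolume(nc, spec$spacing, "non_contrast"),
       iodine = ImageVolume(io, spec$spacing, "iodine"),
       mask = RoiMask(mask),
       composition = spec$composition,
       compartments = comp,
       index = heterogeneityIndex(spec$composition))
}

#' Specification of a synthetic cohort
#'
#' @param nTumors number of tumors.
#' @param countProbs probabilities over mixture sizes 1-4 (default: the
#'   frequencies 19/54/14/2 out of 89 observed in a published resected
#'   adenocarcinoma cohort).
#' @param noiseSd additive HU noise per phantom.
#' @param seed master RNG seed.
#' @return list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nTumors, countProbs = DEFAULT_SUBTYPE_COUNT_PROBS,
                       noiseSd = 20, seed = 1L) {
  stopifnot(nTumors >= 1, length(countProbs) == 4L,
            abs(sum(countProbs) - 1) < 1e-8)
  structure(list(nTumors = as.integer(nTumors),
                 countProbs = as.numeric(countProbs),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Generate a synthetic cohort of dual-energy phantoms
#'
#' Draws each tumor's mixture size from the cohort distribution, samples a
#' composition and grid size (ellipsoid radii 7-12 voxels per axis at 1 mm
#' spacing, matching the 1-4 cm tumors of early-stage resection cohorts),
#' and generates both channels per tumor. With \code{outDir} set, volumes
#' and masks are written as NIfTI, the pathology table as CSV, and a
#' manifest JSON records per-tumor files, seeds and ground truth; otherwise
#' phantoms are returned in memory.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param outDir optional output directory.
#' @return list with \code{phantoms} (NULL when written to disk),
#'   \code{pathology} (data.frame), \code{manifest} (data.frame of file
#'   paths when written), \code{index} (ground-truth indices),
#'   \code{group} (factor), \code{seed}.
#' @export
makeCohort <- function(spec, outDir = NULL) {
  stopifnot(inherits(spec, "cohortSpec"))
  n <- spec$nTumors
  draws <- withSeed(spec$seed, list(
    k = sample.int(4L, n, replace = TRUE, prob = spec$countProbs),
    seeds = sample.int(.Machine$integer.max - 1L, 2L * n)))
  phantoms <- if (is.null(outDir)) vector("list", n) else NULL
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  path <- data.frame(tumor_id = sprintf("T%03d", seq_len(n)),
                     lepidic = 0, acinar = 0, papillary = 0,
                     micropapillary = 0, solid = 0, fibrosis = 0)
  manifest <- NULL
  index <- numeric(n)
  group <- character(n)
  for (i in seq_len(n)) {
    comp <- sampleComposition(draws$k[i], seed = draws$seeds[i])
    radii <- withSeed(draws$seeds[n + i], stats::runif(3, 7, 12))
    shape <- as.integer(2 * ceiling(radii) + 3)
    ps <- phantomSpec(shape = shape, composition = comp,
                      noiseSd = spec$noiseSd, seed = draws$seeds[n + i])
    ph <- makePhantom(ps)
    path[i, SUBTYPES] <- subtypePercent(comp)
    index[i] <- ph$index
    group[i] <- as.character(subtypeCountAndGroup(comp)$group)
    if (is.null(outDir)) {
      phantoms[[i]] <- ph
    } else {
      f <- file.path(outDir, sprintf("%s_%%s.nii.gz", path$tumor_id[i]))
      writeVolume(ph$nonContrast, sprintf(f, "nc"))
      writeVolume(ph$iodine, sprintf(f, "iodine"))
      writeVolume(ph$mask, sprintf(f, "mask"), spacing = ps$spacing)
      manifest <- rbind(manifest, data.frame(
        tumor_id = path$tumor_id[i],
        non_contrast = sprintf(f, "nc"),
        iodine = sprintf(f, "iodine"),
        mask = sprintf(f, "mask"),
        seed = draws$seeds[n + i]))
    }
  }
  group <- factor(group, levels = SUBTYPE_GROUPS)
  if (!is.null(outDir)) {
    utils::write.csv(path, file.path(outDir, "pathology.csv"),
                     row.names = FALSE)
    # file names are stored relative to the manifest so the cohort
    # directory is relocatable and re-runs are byte-identical
    rel <- manifest
    for (col in c("non_contrast", "iodine", "mask"))
      rel[[col]] <- basename(rel[[col]])
    jsonlite::write_json(
      list(seed = spec$seed, n_tumors = n,
           count_probs = spec$countProbs, noise_sd = spec$noiseSd,
           tumors = cbind(rel, index = index,
                          group = as.character(group))),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(phantoms = phantoms, pathology = path, manifest = manifest,
       index = index, group = group, seed = spec$seed)
}
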