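#' The 13 canonical 3D co-occurrence directions
#'
#' The 13 non-collinear nearest-neighbor directions of a 3D grid (half of the
#' 26-neighborhood; the opposite directions are covered by symmetrization).
#'
#' @return 13 x 3 integer matrix of unit offsets.
#' @export
glcmDirections <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y", "z")
  m
}

# Index ranges of source voxels whose offset partner stays on the grid;
# NULL when the offset exceeds the grid extent along any axis.
offsetRanges <- function(d, off) {
  rng <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, 1L - off[a])
    hi <- min(d[a], d[a] - off[a])
    if (hi < lo) return(NULL)
    rng[[a]] <- seq.int(lo, hi)
  }
  rng
}

GLCM_FEATURE_NAMES <- c("energy", "entropy", "correlation", "contrast",
                        "variance", "sum_mean", "inertia", "cluster_shade",
                        "cluster_tendency", "homogeneity",
                        "maximum_probability", "inverse_variance")

#' Build a 3D gray-level co-occurrence matrix for one offset
#'
#' Counts every ordered pair of mask-foreground voxels separated by exactly
#' \code{distance * direction} (voxel units along the offset; anisotropic
#' spacing does not enter), symmetrizes (both (i,j) and (j,i) are counted),
#' and normalizes to probabilities. Pairs with either endpoint outside the
#' mask are ignored. When no valid pair exists, \code{nPairs} is 0 and the
#' matrix is all-zero; callers skip such directions.
#'
#' @param qroi a \linkS4class{QuantizedRoi}.
#' @param direction one of the 13 rows of \code{\link{glcmDirections}}.
#' @param distance integer offset length in voxels (1, 2 or 3).
#' @return list with \code{p} (nLevels x nLevels probability matrix),
#'   \code{offset} (integer 3-vector) and \code{nPairs}.
#' @export
buildGlcm <- function(qroi, direction, distance = 1L) {
  stopifnot(is(qroi, "QuantizedRoi"))
  direction <- as.integer(direction)
  distance <- as.integer(distance)
  if (length(direction) != 3L || !any(direction != 0L) ||
      any(abs(direction) > 1L))
    stop("direction must be a nonzero 3-vector with entries in {-1, 0, 1}")
  if (distance < 1L) stop("distance must be a positive integer")
  off <- direction * distance
  lev <- qroi@levels
  d <- dim(lev)
  n <- qroi@nLevels
  rng <- offsetRanges(d, off)
  empty <- is.null(rng)
  if (!empty) {
    a1 <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    a2 <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
              drop = FALSE]
    sel <- a1 > 0L & a2 > 0L
  }
  if (empty || !any(sel)) {
    return(list(p = matrix(0, n, n), offset = off, nPairs = 0L))
  }
  i <- a1[sel]
  j <- a2[sel]
  counts <- tabulate((i - 1L) * n + j, nbins = n * n)
  C <- t(matrix(counts, n, n))           # C[i, j] = #(pairs level i -> j)
  S <- C + t(C)
  list(p = S / sum(S), offset = off, nPairs = 2L * sum(C))
}

#' Local texture features of one co-occurrence matrix
#'
#' Computes the 12 local features from a symmetric co-occurrence probability
#' matrix p, with marginal means/SDs mu_x, mu_y, sigma_x, sigma_y:
#' energy = sum p^2; entropy = -sum p log2 p (0 log 0 = 0);
#' correlation = sum (i - mu_x)(j - mu_y) p / (sigma_x sigma_y);
#' contrast = sum |i - j| p (first-order difference moment);
#' variance = sum (i - mu_x)^2 p; sum_mean = sum_k k p_(x+y)(k);
#' inertia = sum (i - j)^2 p (second-order difference moment);
#' cluster_shade = sum (i + j - mu_x - mu_y)^3 p;
#' cluster_tendency = sum (i + j - mu_x - mu_y)^2 p;
#' homogeneity = sum p / (1 + |i - j|); maximum_probability = max p;
#' inverse_variance = sum over i != j of p / (i - j)^2.
#' When only one level is occupied the marginal SD is 0 and correlation is
#' reported missing (NA); all other features remain defined.
#'
#' @param glcm a matrix as returned by \code{\link{buildGlcm}}, or the list
#'   itself.
#' @return named numeric(12) in the order of \code{GLCM_FEATURE_NAMES}.
#' @export
glcmFeatures <- function(glcm) {
  p <- if (is.list(glcm)) glcm$p else glcm
  if (is.list(glcm) && glcm$nPairs == 0L)
    stop("empty co-occurrence matrix (nPairs = 0): no features defined")
  n <- nrow(p)
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(n) * px)
  muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - muy)^2 * py))
  pos <- p > 0
  ent <- -sum(p[pos] * log2(p[pos]))
  corr <- if (sx > 0 && sy > 0)
    sum((i - mux) * (j - muy) * p) / (sx * sy) else NA_real_
  offdiag <- i != j
  c(energy = sum(p^2),
    entropy = ent,
    correlation = corr,
    contrast = sum(abs(i - j) * p),
    variance = sum((i - mux)^2 * p),
    sum_mean = sum((i + j) * p),
    inertia = sum((i - j)^2 * p),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    cluster_tendency = sum((i + j - mux - muy)^2 * p),
    homogeneity = sum(p / (1 + abs(i - j))),
    maximum_probability = max(p),
    inverse_variance = sum(p[offdiag] / (i[offdiag] - j[offdiag])^2))
}

#' Direction-aggregated local texture features at one distance
#'
#' Builds the co-occurrence matrix for each of the 13 canonical directions at
#' the given voxel distance, computes the 12 local features per direction,
#' and returns their unweighted mean over the directions that contributed at
#' least one voxel pair (the common radiomics convention of averaging feature
#' values, not matrices). Directions whose offset never stays inside the
#' mask are dropped; if a direction yields a missing correlation (single
#' occupied level) the mean correlation is taken over the defined directions.
#'
#' @param qroi a \linkS4class{QuantizedRoi}.
#' @param distance integer voxel distance (1, 2 or 3).
#' @return named numeric(12) with attribute \code{nDirections} giving the
#'   number of contributing directions.
#' @export
aggregateGlcmFeatures <- function(qroi, distance = 1L) {
  dirs <- glcmDirections()
  rows <- vector("list", nrow(dirs))
  used <- 0L
  for (k in seq_len(nrow(dirs))) {
    g <- buildGlcm(qroi, dirs[k, ], distance)
    if (g$nPairs == 0L) next
    used <- used + 1L
    rows[[used]] <- glcmFeatures(g)
  }
  if (used == 0L)
    stop("no direction produced a valid voxel pair at distance ", distance)
  m <- do.call(rbind, rows[seq_len(used)])
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  attr(out, "nDirections") <- used
  out
}
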