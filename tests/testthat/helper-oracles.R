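# Independent oracles and fixture builders shared across the suite. These
# deliberately use naive algorithms (full pairwise scans, recursive flood
# fill, literal formula transcription) so they share no code path with the
# package implementations they check.

# Wrap an integer level array (0 = background) as a QuantizedRoi.
qroiFromLevels <- function(lev, nLev = max(lev)) {
  new("QuantizedRoi", levels = array(as.integer(lev), dim = dim(lev)),
      nLevels = as.integer(max(2L, nLev)),
      binEdges = seq(0, max(2L, nLev), by = 1))
}

# 4x4x4 checkerboard of levels 1/2 (parity of coordinate sum).
checkerboardQroi <- function(n = 4L) {
  idx <- arrayInd(seq_len(n^3), c(n, n, n))
  lev <- array(1L + (rowSums(idx) %% 2L), dim = c(n, n, n))
  qroiFromLevels(lev, 2L)
}

# Brute-force GLCM: scan every ordered voxel pair (i, j), keep those with
# coordinate difference equal to the offset and both endpoints foreground,
# symmetrize, normalize.
bruteGlcm <- function(lev, off) {
  d <- dim(lev)
  n <- max(max(lev), 2L)
  coords <- arrayInd(seq_along(lev), d)
  fg <- as.vector(lev != 0L)
  match1 <- outer(coords[, 1], coords[, 1], function(a, b) b - a) == off[1]
  match2 <- outer(coords[, 2], coords[, 2], function(a, b) b - a) == off[2]
  match3 <- outer(coords[, 3], coords[, 3], function(a, b) b - a) == off[3]
  pairMat <- match1 & match2 & match3 & outer(fg, fg, `&`)
  C <- matrix(0, n, n)
  hits <- which(pairMat, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    li <- lev[hits[r, 1]]
    lj <- lev[hits[r, 2]]
    C[li, lj] <- C[li, lj] + 1
  }
  S <- C + t(C)
  list(p = if (sum(S) > 0) S / sum(S) else S,
       nPairs = 2L * as.integer(sum(C)))
}

# Literal transcription of the 12 local feature definitions as explicit
# double loops over the matrix entries.
literalGlcmFeatures <- function(p) {
  n <- nrow(p)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum((1:n) * px)
  muy <- sum((1:n) * py)
  sx <- sqrt(sum(((1:n) - mux)^2 * px))
  sy <- sqrt(sum(((1:n) - muy)^2 * py))
  acc <- c(energy = 0, entropy = 0, correlation = 0, contrast = 0,
           variance = 0, sum_mean = 0, inertia = 0, cluster_shade = 0,
           cluster_tendency = 0, homogeneity = 0, maximum_probability = 0,
           inverse_variance = 0)
  for (i in 1:n) for (j in 1:n) {
    v <- p[i, j]
    acc["energy"] <- acc["energy"] + v^2
    if (v > 0) acc["entropy"] <- acc["entropy"] - v * log2(v)
    acc["contrast"] <- acc["contrast"] + abs(i - j) * v
    acc["variance"] <- acc["variance"] + (i - mux)^2 * v
    acc["sum_mean"] <- acc["sum_mean"] + (i + j) * v
    acc["inertia"] <- acc["inertia"] + (i - j)^2 * v
    acc["cluster_shade"] <- acc["cluster_shade"] + (i + j - mux - muy)^3 * v
    acc["cluster_tendency"] <- acc["cluster_tendency"] +
      (i + j - mux - muy)^2 * v
    acc["homogeneity"] <- acc["homogeneity"] + v / (1 + abs(i - j))
    acc["maximum_probability"] <- max(acc["maximum_probability"], v)
    if (i != j)
      acc["inverse_variance"] <- acc["inverse_variance"] + v / (i - j)^2
    if (sx > 0 && sy > 0)
      acc["correlation"] <- acc["correlation"] +
        (i - mux) * (j - muy) * v / (sx * sy)
  }
  if (sx == 0 || sy == 0) acc["correlation"] <- NA_real_
  acc
}

# Recursive flood fill over same-level neighbors; returns the multiset of
# (level, size) zones.
floodZones <- function(lev, connectivity = 26) {
  d <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (start in which(lev != 0L)) {
    if (seen[start]) next
    target <- lev[start]
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (!seen[lin] && lev[lin] == target) {
          seen[lin] <- TRUE
          stack <- c(stack, lin)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(level = target, size = size)
  }
  df <- as.data.frame(do.call(rbind, zones))
  df[order(df$level, df$size), , drop = FALSE]
}

# Exhaustive two-sided Spearman permutation p-value via list-based recursion
# (kept separate from the package's matrix enumeration).
oraclePermutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in oraclePermutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

oracleSpearmanP <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(cor(rx, ry))
  rhos <- vapply(oraclePermutations(seq_along(y)),
                 function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= obs - 1e-12)
}

# A random quantized ROI with background holes.
randomQroi <- function(dims, nLev, pBackground = 0.2) {
  lev <- array(sample(0:nLev, prod(dims), replace = TRUE,
                      prob = c(pBackground, rep((1 - pBackground) / nLev,
                                                nLev))),
               dim = dims)
  if (!any(lev != 0L)) lev[1] <- 1L
  qroiFromLevels(lev, nLev)
}

# RoiSample directly from a value vector (coordinates on a line).
roiFromValues <- function(values, spacing = c(1, 1, 1)) {
  coords <- cbind(x = seq_along(values) - 1L, y = 0L, z = 0L)
  new("RoiSample", values = as.numeric(values), coords = coords,
      spacing = spacing)
}

# Erode a mask by one voxel (6-neighborhood): a second reader tracing just
# inside the boundary, for reader-perturbation stability studies.
erodeMask <- function(mask) {
  m <- voxelData(mask)
  d <- dim(m)
  out <- m
  shift <- function(a, off) {
    rng <- lapply(1:3, function(k)
      seq.int(max(1L, 1L - off[k]), min(d[k], d[k] - off[k])))
    res <- array(FALSE, dim = d)
    res[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3]] <-
      a[rng[[1]], rng[[2]], rng[[3]]]
    res
  }
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
    out <- out & shift(m, off)
  RoiMask(out)
}

# Small in-memory cohort wrapper matching the makeCohort() return shape.
inMemoryCohort <- function(phantoms, pathology) {
  list(phantoms = phantoms, pathology = pathology,
       index = vapply(phantoms, `[[`, 1, "index"),
       group = NULL, manifest = NULL)
}
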