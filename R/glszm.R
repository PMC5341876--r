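#' Build the gray-level size-zone matrix
#'
#' Zones are maximal connected components of equal gray level among
#' foreground voxels; connectivity is 26 (faces, edges and corners, the 3D
#' standard) or 6 (faces only). Entry z[g, s] counts the zones of level g
#' and size s voxels; voxel count is conserved: sum over g, s of s * z[g, s]
#' equals the number of foreground voxels.
#'
#' Component labelling is delegated to a graph decomposition
#' (\code{igraph::components}) over same-level neighbor edges.
#'
#' @param qroi a \linkS4class{QuantizedRoi}.
#' @param connectivity 26 (default) or 6.
#' @return list with \code{z} (nLevels x maxZoneSize integer matrix),
#'   \code{nZones}, and \code{zones} (data.frame of level and size per zone).
#' @export
buildGlszm <- function(qroi, connectivity = 26) {
  stopifnot(is(qroi, "QuantizedRoi"))
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26")
  lev <- qroi@levels
  d <- dim(lev)
  idx <- which(lev != 0L)
  nfg <- length(idx)
  vid <- array(0L, dim = d)
  vid[idx] <- seq_len(nfg)

  dirs <- glcmDirections()
  if (connectivity == 6) dirs <- dirs[rowSums(abs(dirs)) == 1L, , drop = FALSE]
  efrom <- integer(0)
  eto <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    rng <- offsetRanges(d, off)
    if (is.null(rng)) next
    a1 <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    a2 <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
              drop = FALSE]
    v1 <- vid[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    v2 <- vid[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
              drop = FALSE]
    sel <- a1 > 0L & a2 > 0L & a1 == a2
    if (any(sel)) {
      efrom <- c(efrom, v1[sel])
      eto <- c(eto, v2[sel])
    }
  }
  g <- igraph::make_graph(as.integer(rbind(efrom, eto)), n = nfg,
                          directed = FALSE)
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  # level of each zone = level of its first member voxel
  first <- match(seq_len(comp$no), comp$membership)
  zlevel <- lev[idx][first]
  zmat <- matrix(0L, nrow = qroi@nLevels, ncol = max(sizes))
  for (z in seq_along(sizes))
    zmat[zlevel[z], sizes[z]] <- zmat[zlevel[z], sizes[z]] + 1L
  dimnames(zmat) <- list(level = seq_len(qroi@nLevels),
                         size = seq_len(max(sizes)))
  list(z = zmat, nZones = as.integer(comp$no),
       zones = data.frame(level = zlevel, size = sizes))
}

#' Regional features: uniformity, entropy and the two non-uniformities
#'
#' The four regional descriptors:
#' \describe{
#'   \item{uniformity}{sum of squared probabilities of the fine-binned HU
#'     histogram h (default 256 equal-width bins over [-1000, 400] HU).}
#'   \item{regional_entropy}{-sum h log2 h over occupied bins, in bits.}
#'   \item{intensity_variability}{gray-level non-uniformity of the size-zone
#'     matrix: sum over levels g of (sum_s z[g, s])^2 / nZones. Equals 1 when
#'     all zones share one level and grows with level diversity imbalance.}
#'   \item{size_zone_variability}{zone-size non-uniformity:
#'     sum over sizes s of (sum_g z[g, s])^2 / nZones.}
#' }
#' A single-occupied-bin histogram gives uniformity 1 and entropy 0 (no
#' error). The histogram profile is deliberately much finer than the texture
#' quantization so the two entropy scales stay distinct.
#'
#' @param roi a \linkS4class{RoiSample} (for the histogram statistics).
#' @param glszm result of \code{\link{buildGlszm}}.
#' @param nBins number of histogram bins for uniformity/entropy.
#' @param huRange HU window of the histogram profile.
#' @return named numeric(4): uniformity, regional_entropy,
#'   intensity_variability, size_zone_variability.
#' @export
regionalFeatures <- function(roi, glszm, nBins = 256L,
                             huRange = c(-1000, 400)) {
  stopifnot(is(roi, "RoiSample"))
  edges <- seq(huRange[1], huRange[2], length.out = nBins + 1L)
  v <- pmin(pmax(roi@values, huRange[1]), huRange[2])
  bins <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(bins, nbins = nBins) / length(v)
  pos <- h > 0
  z <- glszm$z
  nz <- glszm$nZones
  c(uniformity = sum(h^2),
    regional_entropy = -sum(h[pos] * log2(h[pos])),
    intensity_variability = sum(rowSums(z)^2) / nz,
    size_zone_variability = sum(colSums(z)^2) / nz)
}
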