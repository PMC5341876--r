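#' Physical features: volume, density, mass, size
#'
#' Four physically interpretable descriptors of the segmented tumor:
#' \describe{
#'   \item{volume_cm3}{foreground voxel count times voxel volume, in cm^3.}
#'   \item{density}{mean physical density in g/mL using the standard CT mass
#'     convention density = (HU + 1000)/1000, floored at 0 per voxel.}
#'   \item{mass_g}{volume times density (grams), exact by construction.}
#'   \item{size_mm}{largest in-plane (axial) diameter: the maximum over
#'     axial slices of the largest pairwise distance between foreground
#'     voxel centers, in mm. With \code{size3d = TRUE} the maximum 3D
#'     diameter is returned instead.}
#' }
#'
#' @param roi a \linkS4class{RoiSample}.
#' @param size3d measure size as the 3D maximum diameter instead of the
#'   axial in-plane convention.
#' @return named numeric(4): volume_cm3, density, mass_g, size_mm.
#' @examples
#' vol <- ImageVolume(array(-430, c(10, 10, 10)))
#' msk <- RoiMask(array(TRUE, c(10, 10, 10)))
#' computePhysical(extractRoi(vol, msk))  # volume 1 cm3, density 0.57 g/mL
#' @export
computePhysical <- function(roi, size3d = FALSE) {
  stopifnot(is(roi, "RoiSample"))
  sp <- roi@spacing
  n <- length(roi@values)
  volume <- n * prod(sp) / 1000
  density <- mean(pmax((roi@values + 1000) / 1000, 0))
  c(volume_cm3 = volume,
    density = density,
    mass_g = volume * density,
    size_mm = maxDiameter(roi@coords, sp, in_plane = !size3d))
}

# Largest pairwise distance between voxel centers, per axial slice (z fixed)
# or in full 3D. Convex-hull reduction keeps slices with many voxels cheap.
maxDiameter <- function(coords, sp, in_plane = TRUE) {
  mm <- sweep(coords, 2, sp, `*`)
  if (!in_plane) {
    if (nrow(mm) < 2L) return(0)
    return(maxPairDist(mm))
  }
  best <- 0
  for (z in unique(mm[, 3])) {
    pts <- mm[mm[, 3] == z, 1:2, drop = FALSE]
    if (nrow(pts) < 2L) next
    if (nrow(pts) > 4L) {
      h <- grDevices::chull(pts[, 1], pts[, 2])
      pts <- pts[h, , drop = FALSE]
    }
    best <- max(best, maxPairDist(pts))
  }
  best
}

maxPairDist <- function(pts) {
  max(stats::dist(pts))
}

#' Histogram features: skewness, kurtosis and HU percentiles
#'
#' Seven first-order descriptors of the intratumoral HU distribution:
#' skewness m3/m2^(3/2) and non-excess kurtosis m4/m2^2 (central moments
#' with 1/N normalization, so a normal distribution has kurtosis 3), and the
#' 2.5th, 25th, 50th, 75th and 97.5th percentiles computed by linear
#' interpolation between order statistics (the common "linear" definition).
#' On a zero-variance ROI skewness and kurtosis are reported missing (NA)
#' while the percentiles are still returned.
#'
#' @param roi a \linkS4class{RoiSample}.
#' @return named numeric(7): skewness, kurtosis, hu_p2_5, hu_p25, hu_p50,
#'   hu_p75, hu_p97_5.
#' @export
computeHistogramFeatures <- function(roi) {
  stopifnot(is(roi, "RoiSample"))
  v <- roi@values
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  q <- stats::quantile(v, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                       type = 7, names = FALSE)
  c(skewness = skew, kurtosis = kurt,
    hu_p2_5 = q[1], hu_p25 = q[2], hu_p50 = q[3], hu_p75 = q[4],
    hu_p97_5 = q[5])
}
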