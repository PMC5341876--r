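#' @import methods
NULL

VALID_CHANNELS <- c("non_contrast", "iodine")

#' ImageVolume: a 3D CT grid in Hounsfield units
#'
#' Container for one reconstructed CT channel of a tumor: a 3D array of HU
#' values together with the voxel spacing in mm and a channel tag
#' (\code{"non_contrast"} for the virtual non-contrast reconstruction,
#' \code{"iodine"} for the iodine map).
#'
#' @slot data 3D numeric array of HU values (finite).
#' @slot spacing numeric(3), voxel edge lengths (dx, dy, dz) in mm, all > 0.
#' @slot channel character(1), one of \code{"non_contrast"}, \code{"iodine"}.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", channel = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
      msg <- c(msg, "data must be a 3D array with positive dimensions")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "HU values must all be finite")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 finite positive values (mm)")
    if (length(object@channel) != 1L || !object@channel %in% VALID_CHANNELS)
      msg <- c(msg, sprintf("channel must be one of: %s",
                            paste(VALID_CHANNELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' RoiMask: a binary tumor segmentation on the image grid
#'
#' @slot data 3D array; nonzero entries are foreground. Stored as logical.
#' @export
setClass("RoiMask",
  representation(data = "array"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "mask must be a 3D array")
    if (!is.logical(object@data))
      msg <- c(msg, "mask data must be logical")
    if (!any(object@data))
      msg <- c(msg, "mask must contain at least one foreground voxel")
    if (length(msg)) msg else TRUE
  })

#' RoiSample: HU values and coordinates of the foreground voxels
#'
#' @slot values numeric, HU values at foreground voxels in deterministic
#'   (column-major, x-fastest) order.
#' @slot coords integer matrix (n x 3) of 0-based voxel coordinates.
#' @slot spacing numeric(3) inherited from the source volume (mm).
#' @export
setClass("RoiSample",
  representation(values = "numeric", coords = "matrix", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) < 1L)
      msg <- c(msg, "ROI sample must contain at least one voxel")
    if (nrow(object@coords) != length(object@values) || ncol(object@coords) != 3L)
      msg <- c(msg, "coords must be an n x 3 matrix matching values")
    if (anyDuplicated(object@coords))
      msg <- c(msg, "voxel coordinates must be unique")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values")
    if (length(msg)) msg else TRUE
  })

#' QuantizedRoi: gray-level discretized ROI on the image grid
#'
#' Foreground voxels carry integer levels in 1..nLevels; background voxels
#' carry the sentinel 0. Used by the co-occurrence and size-zone stages.
#'
#' @slot levels 3D integer array, 0 outside the mask.
#' @slot nLevels integer(1), number of gray levels (>= 2).
#' @slot binEdges numeric(nLevels + 1), strictly increasing HU bin edges.
#' @export
setClass("QuantizedRoi",
  representation(levels = "array", nLevels = "integer", binEdges = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nLevels < 2L)
      msg <- c(msg, "nLevels must be >= 2")
    fg <- object@levels[object@levels != 0L]
    if (length(fg) == 0L)
      msg <- c(msg, "quantized ROI has no foreground voxels")
    else if (any(fg < 1L | fg > object@nLevels))
      msg <- c(msg, "foreground levels must lie in [1, nLevels]")
    if (length(object@binEdges) != object@nLevels + 1L ||
        any(diff(object@binEdges) <= 0))
      msg <- c(msg, "binEdges must be strictly increasing, length nLevels + 1")
    if (length(msg)) msg else TRUE
  })

#' SubtypeComposition: histologic growth-pattern percentages of one tumor
#'
#' Percentages of the five IASLC/ATS/ERS invasive adenocarcinoma growth
#' patterns, each a multiple of 5 summing to exactly 100; central fibrosis is
#' stored separately and excluded from the subtype simplex.
#'
#' @slot percent named numeric(5) over lepidic, acinar, papillary,
#'   micropapillary, solid; multiples of 5 in [0, 100] summing to 100.
#' @slot fibrosis numeric(1), fibrosis percentage (NA when not recorded).
#' @export
setClass("SubtypeComposition",
  representation(percent = "numeric", fibrosis = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@percent), SUBTYPES))
      msg <- c(msg, sprintf("percent must be named exactly: %s",
                            paste(SUBTYPES, collapse = ", ")))
    if (any(object@percent < 0 | object@percent > 100) ||
        any(object@percent %% 5 != 0))
      msg <- c(msg, "percentages must be multiples of 5 in [0, 100]")
    if (sum(object@percent) != 100)
      msg <- c(msg, "subtype percentages must sum to exactly 100")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s]: %d x %d x %d voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              object@channel, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("RoiMask: %d x %d x %d grid, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "RoiSample", function(object) {
  cat(sprintf("RoiSample: %d voxels, HU range [%.1f, %.1f], spacing %s mm\n",
              length(object@values), min(object@values), max(object@values),
              paste(format(object@spacing, digits = 3), collapse = " x ")))
})

setMethod("show", "QuantizedRoi", function(object) {
  cat(sprintf("QuantizedRoi: %d levels over HU [%.1f, %.1f], %d foreground voxels\n",
              object@nLevels, object@binEdges[1],
              object@binEdges[length(object@binEdges)],
              sum(object@levels != 0L)))
})

setMethod("show", "SubtypeComposition", function(object) {
  pos <- object@percent[object@percent > 0]
  cat(sprintf("SubtypeComposition: %s%s\n",
              paste(sprintf("%s %d%%", names(pos), pos), collapse = " + "),
              if (is.na(object@fibrosis)) "" else
                sprintf(" (fibrosis %d%%)", object@fibrosis)))
})

#' @describeIn ImageVolume-class constructor.
#' @param data 3D numeric array of HU values.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param channel channel tag.
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1),
                        channel = c("non_contrast", "iodine")) {
  channel <- match.arg(channel)
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      channel = channel)
}

#' @describeIn RoiMask-class constructor; any nonzero entry is foreground.
#' @param data 3D array (logical or numeric).
#' @export
RoiMask <- function(data) {
  new("RoiMask", data = array(data != 0, dim = dim(data)))
}

#' Voxel spacing accessor
#' @param x an ImageVolume or RoiSample.
#' @return numeric(3) spacing in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname spacing
setMethod("spacing", "RoiSample", function(x) x@spacing)

#' Image channel accessor
#' @param x an ImageVolume.
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname channel
setMethod("channel", "ImageVolume", function(x) x@channel)

#' Raw voxel data accessor
#' @param x an ImageVolume, RoiMask or QuantizedRoi.
#' @return the underlying 3D array (HU, logical, or integer levels).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname voxelData
setMethod("voxelData", "ImageVolume", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "RoiMask", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "QuantizedRoi", function(x) x@levels)

#' ROI sample accessors
#' @param x a RoiSample.
#' @return \code{roiValues}: numeric HU values; \code{roiCoords}: n x 3
#'   integer matrix of 0-based voxel coordinates.
#' @export
roiValues <- function(x) {
  stopifnot(is(x, "RoiSample"))
  x@values
}

#' @rdname roiValues
#' @export
roiCoords <- function(x) {
  stopifnot(is(x, "RoiSample"))
  x@coords
}

#' Quantization accessors
#' @param x a QuantizedRoi.
#' @export
nLevels <- function(x) {
  stopifnot(is(x, "QuantizedRoi"))
  x@nLevels
}

#' @rdname nLevels
#' @export
binEdges <- function(x) {
  stopifnot(is(x, "QuantizedRoi"))
  x@binEdges
}

#' Composition accessors
#' @param x a SubtypeComposition.
#' @return \code{subtypePercent}: named numeric(5) percentages;
#'   \code{fibrosisPercent}: fibrosis percentage or NA.
#' @export
subtypePercent <- function(x) {
  stopifnot(is(x, "SubtypeComposition"))
  x@percent
}

#' @rdname subtypePercent
#' @export
fibrosisPercent <- function(x) {
  stopifnot(is(x, "SubtypeComposition"))
  x@fibrosis
}
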