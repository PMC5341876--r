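#' Read a 3D scalar volume from NIfTI or NRRD
#'
#' Reads a 3D CT volume in Hounsfield units. Voxel spacing is taken from the
#' file header; intensities are returned unmodified (no rescale slope is
#' applied: values are assumed to already be HU). Supported formats are
#' NIfTI-1 (\code{.nii}, \code{.nii.gz}) and NRRD (\code{.nrrd}).
#'
#' @param path path to the image file.
#' @param channel channel tag, \code{"non_contrast"} or \code{"iodine"}.
#' @return an \linkS4class{ImageVolume}.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(ImageVolume(array(0, c(4, 4, 4))), f)
#' readVolume(f)
#' @export
readVolume <- function(path, channel = c("non_contrast", "iodine")) {
  channel <- match.arg(channel)
  if (!file.exists(path))
    stop("cannot read image file (not found): ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    nr <- readNrrd(path)
    dat <- nr$data
    sp <- nr$spacing
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    dat <- unclass(as.array(img))
    nd <- length(dim(dat))
    if (nd == 4L && dim(dat)[4] == 1L) dat <- dat[, , , 1, drop = TRUE]
    if (length(dim(dat)) != 3L)
      stop("expected a 3D scalar image, got ", nd, " dimensions: ", path)
    sp <- RNifti::pixdim(img)[1:3]
  } else {
    stop("unsupported image format (need .nii, .nii.gz or .nrrd): ", path)
  }
  if (length(dim(dat)) != 3L)
    stop("expected a 3D scalar image: ", path)
  storage.mode(dat) <- "double"
  attributes(dat) <- list(dim = dim(dat))
  ImageVolume(dat, spacing = sp, channel = channel)
}

#' Read a binary ROI mask co-registered with a volume
#'
#' Any nonzero voxel is foreground. The mask must live on the same grid as
#' its paired image (no resampling stage is provided); shape agreement is
#' checked at extraction time.
#'
#' @param path path to the mask file (same formats as \code{\link{readVolume}}).
#' @return a \linkS4class{RoiMask}.
#' @export
readMask <- function(path) {
  vol <- readVolume(path, channel = "non_contrast")
  RoiMask(voxelData(vol))
}

#' Write a volume to NIfTI (or a mask, as 0/1)
#'
#' @param x an ImageVolume or RoiMask.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @param spacing spacing override for masks (mm).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, spacing = NULL) {
  if (is(x, "ImageVolume")) {
    dat <- x@data
    sp <- x@spacing
  } else if (is(x, "RoiMask")) {
    dat <- array(as.integer(x@data), dim = dim(x@data))
    sp <- if (is.null(spacing)) c(1, 1, 1) else spacing
  } else stop("x must be an ImageVolume or RoiMask")
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- minimal NRRD support (3D scalar) -------------------------------------
# No installed R package reads NRRD, so a small reader/writer for detached
# 3D scalar data is provided: encodings raw / gzip / ascii, little-endian.

NRRD_TYPES <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8"        = list(what = "integer", size = 1, signed = TRUE),
  "uchar"       = list(what = "integer", size = 1, signed = FALSE),
  "uint8"       = list(what = "integer", size = 1, signed = FALSE),
  "short"       = list(what = "integer", size = 2, signed = TRUE),
  "int16"       = list(what = "integer", size = 2, signed = TRUE),
  "ushort"      = list(what = "integer", size = 2, signed = FALSE),
  "uint16"      = list(what = "integer", size = 2, signed = FALSE),
  "int"         = list(what = "integer", size = 4, signed = TRUE),
  "int32"       = list(what = "integer", size = 4, signed = TRUE),
  "float"       = list(what = "double",  size = 4, signed = TRUE),
  "double"      = list(what = "double",  size = 8, signed = TRUE))

readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic))
    stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("expected a 3D scalar NRRD (dimension: 3), got dimension ",
         fields[["dimension"]], ": ", path)
  sizes <- as.integer(strsplit(fields[["sizes"]], "[[:space:]]+")[[1]])
  type <- fields[["type"]]
  spec <- NRRD_TYPES[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  n <- prod(sizes)
  enc <- tolower(fields[["encoding"]])
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  if (enc %in% c("raw")) {
    vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, what = "raw", n = file.size(path))
    vals <- readBin(memDecompress(comp, type = "gzip"), what = spec$what,
                    n = n, size = spec$size, signed = spec$signed,
                    endian = endian)
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD data shorter than header sizes: ", path)
  sp <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    vecs <- lapply(dirs, function(d)
      as.numeric(strsplit(gsub("[()]", "", d), ",")[[1]]))
    sp <- vapply(vecs, function(v) sqrt(sum(v^2)), numeric(1))
  }
  list(data = array(as.double(vals), dim = sizes), spacing = sp)
}

writeNrrd <- function(data, path, spacing = c(1, 1, 1),
                      encoding = c("raw", "gzip", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(length(dim(data)) == 3L)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(data), collapse = " ")),
           sprintf("spacings: %s", paste(format(spacing, digits = 15),
                                         collapse = " ")),
           "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (encoding == "ascii") {
    writeLines(paste(format(as.double(data), digits = 17), collapse = " "), con)
  } else {
    payload <- writeBin(as.double(data), raw(), size = 8, endian = "little")
    if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
    writeBin(payload, con)
  }
  invisible(path)
}

#' Extract the HU sample inside a mask
#'
#' Returns the HU values at mask-foreground voxels in deterministic
#' column-major order (x varies fastest), together with their 0-based
#' coordinates. Background voxels never enter any downstream computation.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a co-registered \linkS4class{RoiMask}.
#' @return a \linkS4class{RoiSample}.
#' @export
extractRoi <- function(volume, mask) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "RoiMask"))
  if (!identical(dim(volume@data), dim(mask@data)))
    stop("mask shape (", paste(dim(mask@data), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume@data), collapse = "x"), ")")
  idx <- which(mask@data)
  if (length(idx) == 0L) stop("empty ROI: mask has no foreground voxels")
  coords <- arrayInd(idx, dim(mask@data)) - 1L
  colnames(coords) <- c("x", "y", "z")
  new("RoiSample", values = as.numeric(volume@data[idx]), coords = coords,
      spacing = volume@spacing)
}

#' Quantize ROI intensities to discrete gray levels
#'
#' Discretizes HU values at foreground voxels into \code{nLevels} equal-width
#' bins over \code{huRange}; values outside the range are clipped into the
#' extreme bins. Level l covers HU in [edge_l, edge_(l+1)), with the topmost
#' bin closed on the right. Background voxels carry the sentinel 0.
#'
#' The package uses two quantization profiles: a coarse fixed-window texture
#' profile (default here: 16 levels over [-1000, 400] HU) feeding the
#' co-occurrence and size-zone matrices, and a fine 256-bin histogram profile
#' for the regional uniformity/entropy statistics (see
#' \code{\link{regionalFeatures}}). Pass \code{huRange = NULL} to bin over
#' the ROI's observed range instead of a fixed window.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a co-registered \linkS4class{RoiMask}.
#' @param nLevels integer >= 2.
#' @param huRange length-2 (lo, hi) HU window, or NULL for the observed
#'   ROI range (errors on a constant ROI, which has no observable range).
#' @return a \linkS4class{QuantizedRoi}.
#' @export
quantizeRoi <- function(volume, mask, nLevels = 16L, huRange = c(-1000, 400)) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "RoiMask"))
  nLevels <- as.integer(nLevels)
  if (is.na(nLevels) || nLevels < 2L)
    stop("nLevels must be an integer >= 2")
  if (!identical(dim(volume@data), dim(mask@data)))
    stop("mask shape does not match volume shape")
  idx <- which(mask@data)
  if (length(idx) == 0L) stop("empty ROI: mask has no foreground voxels")
  v <- volume@data[idx]
  if (is.null(huRange)) {
    huRange <- range(v)
    if (diff(huRange) == 0)
      stop("constant ROI: observed HU range is degenerate; ",
           "pass an explicit huRange")
  }
  if (length(huRange) != 2L || diff(huRange) <= 0)
    stop("huRange must be (lo, hi) with hi > lo")
  edges <- seq(huRange[1], huRange[2], length.out = nLevels + 1L)
  v <- pmin(pmax(v, huRange[1]), huRange[2])
  lev <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- array(0L, dim = dim(mask@data))
  out[idx] <- as.integer(lev)
  new("QuantizedRoi", levels = out, nLevels = nLevels, binEdges = edges)
}
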