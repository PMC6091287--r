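## Raster, landmark and transform IO.
##
## Images: single-channel PNG or TIFF. PNG decoders return values in [0, 1];
## these are rescaled to the 8-bit range [0, 255] on ingest. TIFF is read
## with native integer values; sources deeper than 8 bits are rescaled to
## [0, 255] with a warning. Masks: PNG with 0/255 semantics. Landmarks:
## headered CSV `x,y`. Transforms: 3-line whitespace-separated text.

#' Read a single-channel image
#'
#' @param path PNG or TIFF file.
#' @param modality `"none"`, `"CT"` or `"TEE"`. Declares the default pixel
#'   spacing: 0.32 mm isotropic for CT, 0.224 mm for TEE, 1 mm otherwise.
#' @param pixelSize optional explicit `(dy, dx)` spacing in mm, overriding
#'   the modality default.
#' @return an [Image2D] with float pixels in [0, 255].
#' @export
readImage2D <- function(path, modality = c("none", "CT", "TEE"),
                        pixelSize = NULL) {
  modality <- match.arg(modality)
  arr <- readRasterFile(path)
  if (length(dim(arr)) == 3L) arr <- collapseChannels(arr, path)
  if (is.null(pixelSize))
    pixelSize <- switch(modality, CT = c(0.32, 0.32),
                        TEE = c(0.224, 0.224), none = c(1, 1))
  image2D(arr, pixelSize = pixelSize)
}

#' Write an image
#'
#' Intensities are clamped to the 8-bit range [0, 255]. PNG quantizes to 8
#' bits; TIFF output (`.tif`/`.tiff`) stores 32-bit floats, preserving
#' fractional intensities.
#'
#' @param image an [Image2D] (or matrix).
#' @param path output file; the extension selects the format.
#' @return `path`, invisibly.
#' @export
writeImage2D <- function(image, path) {
  p <- pmin(pmax(asPixelMatrix(image), 0), 255) / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(p, path, bits.per.sample = 32L)
  } else {
    png::writePNG(p, path)
  }
  invisible(path)
}

#' Read a binary mask
#'
#' @param path PNG (or TIFF) file; pixels > 127 on the 8-bit scale are
#'   foreground.
#' @return a [Mask2D].
#' @export
readMask2D <- function(path) {
  arr <- readRasterFile(path)
  if (length(dim(arr)) == 3L) arr <- collapseChannels(arr, path)
  mask2D(arr > 127)
}

#' Write a binary mask as 0/255 PNG
#'
#' @param mask a [Mask2D] (or logical matrix).
#' @param path output PNG file.
#' @return `path`, invisibly.
#' @export
writeMask2D <- function(mask, path) {
  png::writePNG(asMaskMatrix(mask) * 1.0, path)
  invisible(path)
}

#' Read a landmark triplet from CSV
#'
#' The file must have a header `x,y` and exactly three rows of 0-based
#' pixel coordinates.
#'
#' @param path CSV file.
#' @param image optional [Image2D]; when given, points must lie inside it.
#' @return a [LandmarkTriplet].
#' @export
readLandmarks <- function(path, image = NULL) {
  if (!file.exists(path)) pmrFormatError(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    pmrFormatError(sprintf("'%s': expected columns x,y", path))
  if (nrow(df) != 3L)
    pmrCountError(sprintf("'%s': expected exactly 3 landmark rows, got %d",
                          path, nrow(df)))
  landmarkTriplet(cbind(df$x, df$y),
                  shape = if (!is.null(image)) dim(image))
}

#' Write a landmark triplet to CSV
#'
#' @param lm a [LandmarkTriplet].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(lm, path) {
  p <- landmarkPoints(lm)
  utils::write.csv(data.frame(x = p[, 1], y = p[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write a transform as plain text
#'
#' The format is three lines of three whitespace-separated full-precision
#' floats (row-major homogeneous matrix), chosen for diffability.
#' `readTransform(writeTransform(t))` is the identity to 1e-12.
#'
#' @param t an [Affine2D].
#' @param path text file.
#' @return `writeTransform`: `path` invisibly; `readTransform`: an
#'   [Affine2D].
#' @export
writeTransform <- function(t, path) {
  m <- transformMatrix(t)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  if (!file.exists(path)) pmrFormatError(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))))
  if (length(vals) != 9L || any(is.na(vals)))
    pmrFormatError(sprintf("'%s': expected a 3 x 3 numeric matrix", path))
  affine2D(matrix(vals, nrow = 3, byrow = TRUE))
}

## internal -----------------------------------------------------------------

readRasterFile <- function(path) {
  if (!file.exists(path)) pmrFormatError(sprintf("no such file: %s", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path) * 255
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    arr <- tiff::readTIFF(path, info = TRUE)
    if (is.list(arr)) arr <- arr[[1]]
    bps <- attr(arr, "bits.per.sample")
    if (!is.null(bps) && bps > 8L && bps < 32L)
      warning(sprintf("'%s': bit depth exceeds 8 bits; rescaling to [0, 255]",
                      path))
    arr <- arr * 255  # readTIFF normalizes integer samples to [0, 1]
    attributes(arr) <- list(dim = dim(arr))
    arr
  } else {
    pmrFormatError(sprintf("'%s': unsupported raster format (need PNG/TIFF)",
                           path))
  }
}

## Accept multi-channel rasters only when all channels agree (gray stored as
## RGB); a genuine color image has no defined conversion rule here.
collapseChannels <- function(arr, path) {
  ch <- dim(arr)[3]
  base <- arr[, , 1]
  for (k in seq_len(ch)[-1]) {
    if (max(abs(arr[, , k] - base)) > 1e-9) {
      if (k == 4L && ch == 4L) next  # fully opaque alpha handled below
      pmrFormatError(sprintf(
        "'%s': multi-channel image with differing channels; convert to grayscale first",
        path))
    }
  }
  base
}
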