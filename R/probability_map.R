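## Region-enhanced probability maps — the core of the method.
##
## A constant offset (the enhancement level) is added inside the segmented
## region of interest, which pushes foreground intensity bins away from
## background bins without touching spatial structure. A per-intensity
## density — the fraction of pixels of each intensity that lie inside the
## ROI — is then estimated directly from the enhanced image and applied as
## a lookup table, yielding a map of ROI-membership probabilities. Both
## modalities are mapped into this common probability domain, where mutual
## information is far better behaved than on raw intensities.
##
## Enhanced intensities are deliberately NOT clipped at 255: clipping would
## merge enhanced foreground bins with bright background bins and destroy
## exactly the separation the density estimate relies on. The working
## intensity domain is the integers [0, 255 + level].

#' Build an enhancement matrix
#'
#' @param shape output `(h, w)`.
#' @param roi a [Mask2D] (or logical matrix) with `parent_shape == shape`.
#' @param level enhancement constant in gray levels (the published
#'   operating point uses 80 for the CT side and 100 for the TEE side).
#' @return a matrix holding `level` inside the ROI and 0 elsewhere.
#' @export
buildEnhancement <- function(shape, roi, level) {
  b <- asMaskMatrix(roi)
  if (!identical(dim(b), as.integer(shape)))
    pmrShapeError("ROI shape does not match the requested shape")
  if (level < 0) pmrInputError("enhancement level must be >= 0")
  b * as.numeric(level)
}

#' Add an enhancement matrix to an image
#'
#' Pixelwise sum, unclipped; the spatial relationship between pixels is
#' unchanged.
#'
#' @param image an [Image2D] or matrix.
#' @param v enhancement matrix (same shape), from [buildEnhancement()].
#' @return same type as `image`, with summed intensities.
#' @export
enhanceImage <- function(image, v) {
  p <- asPixelMatrix(image)
  v <- asPixelMatrix(v)
  if (!identical(dim(p), dim(v)))
    pmrShapeError("image and enhancement matrix shapes differ")
  out <- p + v
  if (is(image, "Image2D")) image2D(out, pixelSize = pixelSize(image)) else out
}

#' Estimate the per-intensity ROI-membership density
#'
#' For every integer intensity `i` present in the enhanced image, the
#' probability is the count of ROI pixels with intensity `i` divided by the
#' count of all pixels with intensity `i` (a fraction in [0, 1]; the
#' percentage is a display unit). Intensities are binned by rounding to the
#' nearest integer.
#'
#' @param enhanced an enhanced [Image2D] or matrix.
#' @param roi a non-empty [Mask2D] (or logical matrix) of the same shape.
#' @return a [DensityTable].
#' @export
estimateDensity <- function(enhanced, roi) {
  p <- round(asPixelMatrix(enhanced))
  b <- asMaskMatrix(roi)
  if (!identical(dim(p), dim(b)))
    pmrShapeError("image and ROI shapes differ")
  if (!any(b)) pmrInputError("ROI mask is empty")
  lo <- min(p)
  idx <- as.integer(p - lo) + 1L            # 1-based bin index
  nbin <- max(idx)
  totals <- tabulate(idx, nbins = nbin)
  inRoi <- tabulate(idx[b], nbins = nbin)
  seen <- which(totals > 0L)
  new("DensityTable", intensities = as.integer(seen - 1L + lo),
      probs = inRoi[seen] / totals[seen])
}

#' Apply a density table to an enhanced image
#'
#' Each pixel's intensity (rounded to the nearest integer) is looked up in
#' the table; intensities never seen at estimation time map to 0.
#'
#' @param enhanced an enhanced [Image2D] or matrix.
#' @param table a [DensityTable].
#' @return a [ProbabilityMap2D] of the same shape.
#' @export
applyDensity <- function(enhanced, table) {
  p <- round(asPixelMatrix(enhanced))
  hit <- match(as.integer(p), table@intensities)
  vals <- ifelse(is.na(hit), 0, table@probs[hit])
  new("ProbabilityMap2D", values = matrix(vals, nrow(p), ncol(p)))
}

#' Build the region-enhanced probability map of one image
#'
#' Composes [buildEnhancement()], [enhanceImage()], [estimateDensity()] and
#' [applyDensity()]: one call per modality, with `level = N` for the
#' reference (CT-side) image and `level = M` for the floating (TEE-side)
#' image.
#'
#' @inheritParams buildEnhancement
#' @param image an [Image2D] or matrix.
#' @param roi the image's foreground segmentation.
#' @return a [ProbabilityMap2D].
#' @export
makeProbabilityMap <- function(image, roi, level) {
  p <- asPixelMatrix(image)
  v <- buildEnhancement(dim(p), roi, level)
  enhanced <- p + v
  applyDensity(enhanced, estimateDensity(enhanced, roi))
}
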