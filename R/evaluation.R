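## Quantitative evaluation: Dice overlap and RMS target registration error
## against a reference transform (a phantom's generating transform, or any
## user-supplied bronze-standard registration).

#' Dice overlap coefficient between two masks
#'
#' `2 |A and B| / (|A| + |B|)`.
#'
#' @param a,b [Mask2D] (or logical matrices) of the same shape.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  ma <- asMaskMatrix(a); mb <- asMaskMatrix(b)
  if (!identical(dim(ma), dim(mb)))
    pmrShapeError("masks have different shapes")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L)
    pmrMetricError("Dice is undefined: both masks are empty")
  2 * sum(ma & mb) / (na + nb)
}

#' RMS target registration error between two transforms
#'
#' Every ROI-true pixel position is mapped by both the estimated and the
#' reference transform; the root-mean-square Euclidean distance between the
#' two mapped positions is returned in mm of fixed-image space. The ROI
#' lives in the transforms' domain (the moving image).
#'
#' @param roi a non-empty [Mask2D] (or logical matrix) of evaluation
#'   points.
#' @param tEst,tRef estimated and reference [Affine2D] (moving -> fixed).
#' @param pixelSize fixed-image spacing `(dy, dx)` in mm/pixel; with
#'   anisotropic spacing each axis is scaled before the norm.
#' @return RMS distance in mm.
#' @export
treRMS <- function(roi, tEst, tRef, pixelSize = c(1, 1)) {
  b <- asMaskMatrix(roi)
  if (!any(b)) pmrInputError("ROI mask is empty")
  idx <- which(b) - 1L
  h <- nrow(b)
  pts <- cbind(x = idx %/% h, y = idx %% h)
  d <- applyTransform(tEst, pts) - applyTransform(tRef, pts)
  dxmm <- d[, 1] * pixelSize[2]
  dymm <- d[, 2] * pixelSize[1]
  sqrt(mean(dxmm^2 + dymm^2))
}

#' Evaluate a registration run against a reference transform
#'
#' Dice is computed between the ROI warped into fixed space by the
#' estimated and by the reference transform (nearest-neighbor mask
#' warping); TRE is the RMS mapped-point distance over the same ROI.
#'
#' @param result a [RegistrationResult].
#' @param roi moving-image foreground [Mask2D] to evaluate over.
#' @param tRef reference [Affine2D] (phantom ground truth or bronze
#'   standard); required, there is no silent fallback.
#' @param pixelSize fixed-image spacing `(dy, dx)` in mm/pixel; defaults to
#'   the result's resampled-image spacing.
#' @param reference label recorded in the report.
#' @return an [EvaluationReport].
#' @export
evaluateRun <- function(result, roi, tRef, pixelSize = NULL,
                        reference = "ground_truth") {
  if (missing(tRef) || is.null(tRef))
    pmrInputError("a reference transform is required")
  if (is.null(pixelSize)) pixelSize <- pixelSize(result@sFinal)
  outShape <- dim(result@sFinal)
  wEst <- warpMask(roi, result@tFinal, outShape)
  wRef <- warpMask(roi, tRef, outShape)
  new("EvaluationReport",
      dice = diceCoefficient(wEst, wRef),
      treRmsMm = treRMS(roi, result@tFinal, tRef, pixelSize),
      nPoints = as.integer(sum(asMaskMatrix(roi))),
      reference = reference)
}
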