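## Normalized mutual information (Studholme's form).
##
## NMI(A, B) = (H(A) + H(B)) / H(A, B) from a bins x bins joint histogram
## accumulated over the valid overlap region, with each marginal
## range-normalized over that region. The value lies in [1, 2]: 2 for
## identical non-constant inputs, -> 1 for independent ones. Out-of-footprint
## fill pixels must be excluded via the validity mask — counting them would
## fabricate correlation between the fill value and the fixed image.

#' Normalized mutual information between two images or probability maps
#'
#' @param a,b [Image2D], [ProbabilityMap2D] or matrices of the same shape.
#' @param bins histogram bins per axis (default 64).
#' @param valid optional [Mask2D] (or logical matrix) restricting the
#'   computation to valid overlap pixels.
#' @return NMI value in [1, 2].
#' @export
nmi <- function(a, b, bins = 64L, valid = NULL) {
  pa <- asPixelMatrix(a); pb <- asPixelMatrix(b)
  if (!identical(dim(pa), dim(pb)))
    pmrShapeError("inputs have different shapes")
  if (is.null(valid)) {
    va <- as.vector(pa); vb <- as.vector(pb)
  } else {
    v <- asMaskMatrix(valid)
    if (!identical(dim(v), dim(pa)))
      pmrShapeError("validity mask shape differs from the inputs")
    if (!any(v)) pmrInputError("validity mask is empty")
    va <- pa[v]; vb <- pb[v]
  }
  nmiFromVectors(va, vb, as.integer(bins), onDegenerate = "error")
}

## Fast path shared with the optimizer. onDegenerate = "error" raises a
## condition for constant inputs; "worst" returns NMI = 1 (used for trial
## steps whose overlap degenerates).
nmiFromVectors <- function(va, vb, bins, onDegenerate = c("error", "worst")) {
  onDegenerate <- match.arg(onDegenerate)
  ra <- range(va); rb <- range(vb)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    if (onDegenerate == "worst") return(1.0)
    pmrDegenerateError("input is constant over the valid region (zero entropy)")
  }
  ia <- pmin.int(as.integer((va - ra[1]) / (ra[2] - ra[1]) * bins), bins - 1L)
  ib <- pmin.int(as.integer((vb - rb[1]) / (rb[2] - rb[1]) * bins), bins - 1L)
  n <- length(ia)
  joint <- tabulate(ia + bins * ib + 1L, nbins = bins * bins)
  pj <- joint[joint > 0L] / n
  hj <- -sum(pj * log(pj))
  ca <- tabulate(ia + 1L, nbins = bins); pa <- ca[ca > 0L] / n
  cb <- tabulate(ib + 1L, nbins = bins); pb <- cb[cb > 0L] / n
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  (ha + hb) / hj
}
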