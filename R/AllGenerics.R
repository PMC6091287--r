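#' @rdname Image2D-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname Image2D-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname Mask2D-class
#' @export
setGeneric("maskBits", function(x) standardGeneric("maskBits"))

#' @rdname LandmarkTriplet-class
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))

#' @rdname Affine2D-class
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @rdname ProbabilityMap2D-class
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))

#' Apply a planar transform to points
#'
#' Maps 0-based pixel coordinates of the moving image into fixed-image
#' coordinates.
#'
#' @param t an [Affine2D].
#' @param points numeric n x 2 matrix with columns `x`, `y` (a length-2
#'   vector is treated as one point).
#' @return numeric n x 2 matrix of mapped coordinates.
#' @export
setGeneric("applyTransform", function(t, points) standardGeneric("applyTransform"))
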