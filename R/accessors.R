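## Constructors, accessors and show methods for the core types.

#' Create an Image2D
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixelSize physical spacing `(dy, dx)` in mm/pixel.
#' @return an [Image2D].
#' @export
image2D <- function(pixels, pixelSize = c(1, 1)) {
  new("Image2D", pixels = asNumericMatrix(pixels),
      pixelSize = as.numeric(pixelSize))
}

#' Create a Mask2D
#'
#' @param bits logical matrix (numeric input is thresholded at > 0).
#' @return a [Mask2D].
#' @export
mask2D <- function(bits) {
  if (is.numeric(bits)) bits <- bits > 0
  storage.mode(bits) <- "logical"
  new("Mask2D", bits = bits)
}

#' Create a LandmarkTriplet
#'
#' @param points numeric 3 x 2 matrix, columns `x`, `y` (0-based pixel
#'   coordinates).
#' @param shape optional image shape `(h, w)`; when given, points must lie
#'   inside `[0, w-1] x [0, h-1]`.
#' @return a [LandmarkTriplet].
#' @export
landmarkTriplet <- function(points, shape = NULL) {
  points <- asNumericMatrix(points)
  if (!identical(dim(points), c(3L, 2L)))
    pmrCountError("a landmark triplet needs exactly 3 (x, y) points")
  colnames(points) <- c("x", "y")
  if (!is.null(shape)) {
    h <- shape[1]; w <- shape[2]
    inb <- points[, 1] >= 0 & points[, 1] <= w - 1 &
           points[, 2] >= 0 & points[, 2] <= h - 1
    if (!all(inb))
      pmrBoundsError(sprintf(
        "landmark %d is outside the %d x %d image", which(!inb)[1], h, w))
  }
  if (abs(signedDoubledArea(points)) <= 1e-6)
    pmrGeometryError("landmarks are collinear")
  new("LandmarkTriplet", points = points)
}

#' Create an Affine2D
#'
#' @param m numeric 3 x 3 homogeneous matrix (last row (0, 0, 1)), or a
#'   2 x 3 matrix which is completed with that row.
#' @return an [Affine2D].
#' @export
affine2D <- function(m) {
  m <- asNumericMatrix(m)
  if (identical(dim(m), c(2L, 3L))) m <- rbind(m, c(0, 0, 1))
  if (!identical(dim(m), c(3L, 3L)))
    pmrFormatError("transform matrix must be 3 x 3 (or 2 x 3)")
  obj <- try(new("Affine2D", matrix = unname(m)), silent = TRUE)
  if (inherits(obj, "try-error"))
    pmrGeometryError(attr(obj, "condition")$message)
  obj
}

#' Identity transform
#' @return the identity [Affine2D].
#' @export
identityTransform <- function() affine2D(diag(3))

#' @rdname Image2D-class
#' @export
setMethod("pixels", "Image2D", function(x) x@pixels)

#' @rdname Image2D-class
#' @export
setMethod("pixelSize", "Image2D", function(x) x@pixelSize)

#' @rdname Image2D-class
#' @export
setMethod("dim", "Image2D", function(x) dim(x@pixels))

#' @rdname Mask2D-class
#' @export
setMethod("maskBits", "Mask2D", function(x) x@bits)

#' @rdname Mask2D-class
#' @export
setMethod("dim", "Mask2D", function(x) dim(x@bits))

#' @rdname LandmarkTriplet-class
#' @export
setMethod("landmarkPoints", "LandmarkTriplet", function(x) x@points)

#' @rdname Affine2D-class
#' @export
setMethod("transformMatrix", "Affine2D", function(x) x@matrix)

#' @rdname ProbabilityMap2D-class
#' @export
setMethod("probValues", "ProbabilityMap2D", function(x) x@values)

#' @rdname ProbabilityMap2D-class
#' @export
setMethod("dim", "ProbabilityMap2D", function(x) dim(x@values))

#' @rdname Affine2D-class
#' @param points numeric n x 2 matrix of (x, y) points.
#' @export
setMethod("applyTransform", "Affine2D", function(t, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- asNumericMatrix(points)
  m <- t@matrix
  out <- cbind(points, 1) %*% t(m[1:2, , drop = FALSE])
  colnames(out) <- c("x", "y")
  out
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D: %d x %d px, spacing (%.4g, %.4g) mm, range [%.4g, %.4g]\n",
              d[1], d[2], object@pixelSize[1], object@pixelSize[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "Mask2D", function(object) {
  d <- dim(object@bits)
  cat(sprintf("Mask2D: %d x %d px, %d foreground pixels (%.1f%%)\n",
              d[1], d[2], sum(object@bits),
              100 * mean(object@bits)))
})

setMethod("show", "LandmarkTriplet", function(object) {
  cat("LandmarkTriplet (x, y):\n")
  print(round(object@points, 3))
})

setMethod("show", "Affine2D", function(object) {
  cat("Affine2D (moving -> fixed):\n")
  print(signif(object@matrix, 6))
})

setMethod("show", "DensityTable", function(object) {
  cat(sprintf("DensityTable: %d intensity bins, P(ROI) range [%.3f, %.3f]\n",
              length(object@intensities), min(object@probs), max(object@probs)))
})

setMethod("show", "ProbabilityMap2D", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityMap2D: %d x %d px, mean probability %.3f\n",
              d[1], d[2], mean(object@values)))
})

setMethod("show", "RegistrationConfig", function(object) {
  cat(sprintf(paste0(
    "RegistrationConfig: N=%g M=%g bins=%d model=%s\n",
    "  Powell: xtol=%g maxIter=%d; metric interp=%s; seed=%d\n"),
    object@N, object@M, object@nmiBins, object@transformModel,
    object@powellXtol, object@powellMaxIter, object@metricInterp,
    object@seed))
})

setMethod("show", "BasicResult", function(object) {
  cat(sprintf("BasicResult: landmark residual %.3g px\n", object@residual))
  show(object@tBasic)
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(
    "RegistrationResult (%s): NMI %.4f -> %.4f in %d Powell iterations (%d evaluations)\n",
    object@mode, object@nmiInitial, object@nmiFinal, object@iterations,
    object@evaluations))
  show(object@tFinal)
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport vs %s: Dice %.4f, TRE (RMS) %.4f mm over %d points\n",
    object@reference, object@dice, object@treRmsMm, object@nPoints))
})

setMethod("show", "PhantomPair", function(object) {
  cat(sprintf("PhantomPair (seed %d):\n", object@seed))
  cat("  fixed:  "); show(object@fixed)
  cat("  moving: "); show(object@moving)
})

#' Registration settings constructor
#'
#' Defaults follow the method's published operating point: enhancement
#' levels `N = 80` (reference side) and `M = 100` (floating side), with
#' standard choices for the similarity histogram and optimizer.
#'
#' @param N,M region-enhancement levels for the reference and floating
#'   image, in gray levels.
#' @param nmiBins histogram bins per axis for normalized mutual information.
#' @param powellXtol convergence tolerance on the scaled parameter vector.
#' @param powellMaxIter iteration cap for Powell's method.
#' @param transformModel `"affine6"` or `"rigid_scale4"`.
#' @param metricInterp `"linear"` or `"cubic"` warping inside the metric loop.
#' @param seed integer seed for any stochastic component.
#' @return a [RegistrationConfig].
#' @export
registrationConfig <- function(N = 80, M = 100, nmiBins = 64L,
                               powellXtol = 1e-4, powellMaxIter = 100L,
                               transformModel = c("affine6", "rigid_scale4"),
                               metricInterp = c("linear", "cubic"),
                               seed = 0L) {
  new("RegistrationConfig", N = as.numeric(N), M = as.numeric(M),
      nmiBins = as.integer(nmiBins), powellXtol = as.numeric(powellXtol),
      powellMaxIter = as.integer(powellMaxIter),
      transformModel = match.arg(transformModel),
      metricInterp = match.arg(metricInterp), seed = as.integer(seed))
}

## internal helpers ---------------------------------------------------------

asNumericMatrix <- function(m) {
  if (!is.matrix(m)) pmrFormatError("expected a matrix")
  storage.mode(m) <- "double"
  m
}

## Twice the signed area of the triangle spanned by three (x, y) rows.
signedDoubledArea <- function(p) {
  (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
}

## Extract a plain numeric matrix from Image2D / ProbabilityMap2D / matrix.
asPixelMatrix <- function(x) {
  if (is(x, "Image2D")) return(x@pixels)
  if (is(x, "ProbabilityMap2D")) return(x@values)
  if (is.matrix(x)) return(asNumericMatrix(x))
  pmrFormatError("expected an Image2D, ProbabilityMap2D or matrix")
}

asMaskMatrix <- function(x) {
  if (is(x, "Mask2D")) return(x@bits)
  if (is.matrix(x)) {
    if (is.numeric(x)) x <- x > 0
    storage.mode(x) <- "logical"
    return(x)
  }
  pmrFormatError("expected a Mask2D or matrix")
}
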