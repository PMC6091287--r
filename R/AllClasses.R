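#' @import methods
NULL

## Coordinate convention (used by every operation in the package):
## x = column index, y = row index, both 0-based, pixel centers at integer
## coordinates. A point (x, y) addresses matrix element [y + 1, x + 1].

#' Single-channel 2D image
#'
#' Holds a float-valued pixel matrix together with its physical pixel
#' spacing. Ingested 8-bit data lie in [0, 255]; region-enhanced images may
#' exceed 255 by design (see [enhanceImage()]).
#'
#' @slot pixels numeric matrix of intensities (rows = y, columns = x).
#' @slot pixelSize numeric of length 2, physical spacing `(dy, dx)` in
#'   mm/pixel.
#'
#' @seealso [image2D()], [readImage2D()]
#' @export
setClass("Image2D",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (nrow(p) < 8L || ncol(p) < 8L)
      return("image must be at least 8 x 8 pixels")
    if (!is.numeric(p) || any(!is.finite(p)))
      return("pixel intensities must be finite numerics")
    if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
      return("pixelSize must be two positive values (dy, dx) in mm")
    TRUE
  })

#' Binary foreground mask aligned to an image
#'
#' @slot bits logical matrix, `TRUE` marks foreground (region of interest).
#'
#' @seealso [mask2D()], [readMask2D()]
#' @export
setClass("Mask2D",
  representation(bits = "matrix"),
  validity = function(object) {
    if (!is.logical(object@bits)) return("bits must be a logical matrix")
    if (any(is.na(object@bits))) return("bits must not contain NA")
    TRUE
  })

#' Three landmark points of one image
#'
#' Exactly three non-collinear points in pixel coordinates, e.g. the two
#' endpoints and the midpoint of a heart valve identified interactively.
#'
#' @slot points numeric 3 x 2 matrix with columns `x`, `y` (0-based pixel
#'   coordinates).
#'
#' @seealso [landmarkTriplet()], [readLandmarks()]
#' @export
setClass("LandmarkTriplet",
  representation(points = "matrix"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || !identical(dim(p), c(3L, 2L)))
      return("points must be a numeric 3 x 2 matrix (columns x, y)")
    if (any(!is.finite(p))) return("landmark coordinates must be finite")
    if (abs(signedDoubledArea(p)) <= 1e-6)
      return("landmarks are collinear (|doubled triangle area| <= 1e-6 px^2)")
    TRUE
  })

#' Planar affine transform in homogeneous coordinates
#'
#' A 3 x 3 matrix with last row (0, 0, 1) mapping homogeneous moving-image
#' coordinates `(x, y, 1)` to fixed-image coordinates.
#'
#' @slot matrix numeric 3 x 3 homogeneous matrix.
#'
#' @seealso [affine2D()], [applyTransform()]
#' @export
setClass("Affine2D",
  representation(matrix = "matrix"),
  validity = function(object) {
    m <- object@matrix
    if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
      return("matrix must be numeric 3 x 3")
    if (any(!is.finite(m))) return("matrix entries must be finite")
    if (max(abs(m[3, ] - c(0, 0, 1))) > 1e-9)
      return("last row must be (0, 0, 1)")
    if (abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) <= 1e-12)
      return("upper-left 2 x 2 block is singular (|det| <= 1e-12)")
    TRUE
  })

#' Registration settings
#'
#' @slot N numeric, enhancement level added inside the reference (CT-side)
#'   region of interest before density estimation; default 80.
#' @slot M numeric, enhancement level for the floating (TEE-side) image;
#'   default 100.
#' @slot nmiBins integer, histogram bins per axis for normalized mutual
#'   information; default 64.
#' @slot powellXtol numeric, convergence tolerance on the (scaled) parameter
#'   vector of Powell's method; default 1e-4.
#' @slot powellMaxIter integer, cap on Powell direction-set iterations;
#'   default 100.
#' @slot transformModel `"affine6"` (tx, ty, angle, two scales, shear) or
#'   `"rigid_scale4"` (tx, ty, angle, isotropic scale).
#' @slot metricInterp interpolation used when warping inside the metric
#'   loop; `"linear"` (default, fast) or `"cubic"`.
#' @slot seed integer seed for any stochastic component.
#'
#' @seealso [registrationConfig()]
#' @export
setClass("RegistrationConfig",
  representation(N = "numeric", M = "numeric", nmiBins = "integer",
                 powellXtol = "numeric", powellMaxIter = "integer",
                 transformModel = "character", metricInterp = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@N < 0 || object@M < 0) return("N and M must be >= 0")
    if (object@nmiBins < 8L) return("nmiBins must be >= 8")
    if (object@powellXtol <= 0) return("powellXtol must be > 0")
    if (object@powellMaxIter < 1L) return("powellMaxIter must be >= 1")
    if (!object@transformModel %in% c("affine6", "rigid_scale4"))
      return("transformModel must be 'affine6' or 'rigid_scale4'")
    if (!object@metricInterp %in% c("linear", "cubic"))
      return("metricInterp must be 'linear' or 'cubic'")
    TRUE
  })

#' Per-intensity region-membership probabilities
#'
#' A lookup table from integer intensity to the probability that a pixel of
#' that intensity lies inside the segmented region of interest. Intensities
#' never observed at estimation time map to probability 0.
#'
#' @slot intensities integer vector of observed intensity bins (sorted).
#' @slot probs numeric vector in [0, 1], parallel to `intensities`.
#'
#' @seealso [estimateDensity()], [applyDensity()]
#' @export
setClass("DensityTable",
  representation(intensities = "integer", probs = "numeric"),
  validity = function(object) {
    if (length(object@intensities) != length(object@probs))
      return("intensities and probs must have equal length")
    if (any(object@probs < 0 | object@probs > 1))
      return("probabilities must lie in [0, 1]")
    if (is.unsorted(object@intensities, strictly = TRUE))
      return("intensities must be strictly increasing")
    TRUE
  })

#' Probability map
#'
#' An image-shaped array whose values are region-membership probabilities in
#' [0, 1].
#'
#' @slot values numeric matrix in [0, 1].
#'
#' @seealso [makeProbabilityMap()]
#' @export
setClass("ProbabilityMap2D",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (any(!is.finite(v))) return("values must be finite")
    if (any(v < 0 | v > 1)) return("values must lie in [0, 1]")
    TRUE
  })

#' Result of the coarse landmark-based registration
#'
#' @slot tBasic [Affine2D] solved from the three landmark pairs.
#' @slot resampled [Image2D], the moving image resampled into fixed space.
#' @slot valid [Mask2D] of fixed-space pixels whose source lies inside the
#'   moving image footprint.
#' @slot residual numeric, maximum landmark mapping error in pixels.
#'
#' @seealso [runBasic()]
#' @export
setClass("BasicResult",
  representation(tBasic = "Affine2D", resampled = "Image2D",
                 valid = "Mask2D", residual = "numeric"))

#' Result of the full two-stage registration
#'
#' @slot tBasic coarse transform (warm start).
#' @slot tFinal optimized transform.
#' @slot sFinal final resampled moving image in fixed space.
#' @slot validFinal validity mask of `sFinal`.
#' @slot nmiInitial normalized mutual information at the warm start.
#' @slot nmiFinal normalized mutual information at the optimum.
#' @slot iterations Powell direction-set iterations used.
#' @slot evaluations similarity-metric evaluations used.
#' @slot mode `"probmap"` (probability-map metric) or `"intensity"`
#'   (raw-intensity baseline).
#' @slot trace numeric vector of best-so-far NMI at accepted points.
#' @slot config the [RegistrationConfig] used.
#'
#' @seealso [registerMultimodal()]
#' @export
setClass("RegistrationResult",
  representation(tBasic = "Affine2D", tFinal = "Affine2D",
                 sFinal = "Image2D", validFinal = "Mask2D",
                 nmiInitial = "numeric", nmiFinal = "numeric",
                 iterations = "integer", evaluations = "integer",
                 mode = "character", trace = "numeric",
                 config = "RegistrationConfig"),
  validity = function(object) {
    if (object@nmiFinal < object@nmiInitial - 1e-9)
      return("nmiFinal must not be below nmiInitial")
    if (!object@mode %in% c("probmap", "intensity"))
      return("mode must be 'probmap' or 'intensity'")
    TRUE
  })

#' Quantitative evaluation of a registration
#'
#' @slot dice Dice overlap in [0, 1] between the region warped by the
#'   estimated and by the reference transform.
#' @slot treRmsMm root-mean-square target registration error in mm of
#'   fixed-image space.
#' @slot nPoints number of region pixels evaluated.
#' @slot reference label of the reference-transform source.
#'
#' @seealso [evaluateRun()]
#' @export
setClass("EvaluationReport",
  representation(dice = "numeric", treRmsMm = "numeric",
                 nPoints = "integer", reference = "character"),
  validity = function(object) {
    if (object@dice < 0 || object@dice > 1) return("dice must lie in [0, 1]")
    if (object@treRmsMm < 0) return("treRmsMm must be >= 0")
    if (object@nPoints < 1L) return("nPoints must be >= 1")
    TRUE
  })

#' Phantom generator settings
#'
#' Controls the synthetic pseudo-CT / pseudo-TEE pair generator; see
#' [makePhantomPair()] for the meaning of each field.
#'
#' @slot canvas integer (h, w) of the fixed pseudo-CT canvas.
#' @slot movingCanvas integer (h, w) of the moving pseudo-TEE canvas.
#' @slot rotationRange numeric, max |rotation| in degrees.
#' @slot translationRange numeric, max |translation| per axis in pixels.
#' @slot scaleRange numeric length-2 interval for the two scale factors.
#' @slot shearRange numeric, max |shear| coefficient.
#' @slot speckleStrength numeric >= 0, blending weight of unit-mean
#'   Rayleigh-derived multiplicative speckle (0 = off, 1 = fully developed).
#' @slot gaussianNoiseSd numeric >= 0, additive noise sd on the pseudo-CT
#'   (8-bit gray levels).
#' @slot fanMask logical, apply a fan/sector ultrasound footprint to the
#'   moving image.
#' @slot intensityRemap `"echo_like"` (gamma-darkened levels with the
#'   blood-filled chambers collapsed to near-anechoic values, many-to-one)
#'   or `"identity"`.
#'
#' @seealso [phantomParams()]
#' @export
setClass("PhantomParams",
  representation(canvas = "integer", movingCanvas = "integer",
                 rotationRange = "numeric", translationRange = "numeric",
                 scaleRange = "numeric", shearRange = "numeric",
                 speckleStrength = "numeric", gaussianNoiseSd = "numeric",
                 fanMask = "logical", intensityRemap = "character"),
  validity = function(object) {
    if (any(object@canvas < 64L) || any(object@movingCanvas < 64L))
      return("canvases must be at least 64 x 64")
    if (object@rotationRange < 0 || object@translationRange < 0 ||
        object@shearRange < 0)
      return("ranges must be non-negative")
    if (length(object@scaleRange) != 2L ||
        object@scaleRange[1] <= 0 || diff(object@scaleRange) < 0)
      return("scaleRange must be a positive non-degenerate interval")
    if (object@speckleStrength < 0 || object@gaussianNoiseSd < 0)
      return("noise strengths must be >= 0")
    if (!object@intensityRemap %in% c("echo_like", "identity"))
      return("intensityRemap must be 'echo_like' or 'identity'")
    TRUE
  })

#' Synthetic multimodal image pair with known ground truth
#'
#' @slot fixed pseudo-CT [Image2D].
#' @slot moving pseudo-TEE [Image2D].
#' @slot fixedMask,movingMask foreground [Mask2D] per image.
#' @slot fixedLm,movingLm valve [LandmarkTriplet] per image.
#' @slot tTrue ground-truth [Affine2D] mapping moving to fixed coordinates
#'   (the phantom's stand-in for a bronze-standard registration).
#' @slot seed integer seed the pair was generated from.
#' @slot params the [PhantomParams] used.
#'
#' @seealso [makePhantomPair()]
#' @export
setClass("PhantomPair",
  representation(fixed = "Image2D", moving = "Image2D",
                 fixedMask = "Mask2D", movingMask = "Mask2D",
                 fixedLm = "LandmarkTriplet", movingLm = "LandmarkTriplet",
                 tTrue = "Affine2D", seed = "integer",
                 params = "PhantomParams"))
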