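## Coarse (basic) registration: three valve landmark pairs determine the
## planar affine transform exactly; the moving image is then resampled into
## fixed space with bicubic interpolation.

#' Solve the affine transform mapping three moving landmarks onto three
#' fixed landmarks
#'
#' Three non-collinear point pairs determine a planar affine map uniquely:
#' writing each fixed point as `x_r = T x_f` in homogeneous coordinates
#' gives a linear system solved exactly.
#'
#' @param fixed,moving [LandmarkTriplet] objects in fixed- and moving-image
#'   pixel coordinates.
#' @return an [Affine2D] `T` with `fixed_k = T moving_k` for k = 1..3.
#' @export
solveAffineFromLandmarks <- function(fixed, moving) {
  pf <- landmarkPoints(fixed)
  pm <- landmarkPoints(moving)
  if (anyDuplicated(round(pm, 9)) || anyDuplicated(round(pf, 9)))
    pmrGeometryError("repeated landmark points")
  Pm <- cbind(pm, 1)
  if (abs(det(Pm)) <= 1e-6)
    pmrGeometryError("moving landmarks are collinear")
  ## Pm %*% t(T[1:2, ]) = pf  =>  t(T[1:2, ]) = solve(Pm, pf)
  T12 <- t(solve(Pm, pf))
  affine2D(rbind(T12, c(0, 0, 1)))
}

#' Least-squares affine from n >= 3 point pairs
#'
#' Extension of [solveAffineFromLandmarks()] for more than three
#' correspondences; not used by the standard pipeline, which takes exactly
#' the three valve points.
#'
#' @param fixed,moving numeric n x 2 matrices of (x, y) points, n >= 3.
#' @return an [Affine2D] minimizing the sum of squared mapping errors.
#' @export
solveAffineLeastSquares <- function(fixed, moving) {
  fixed <- asNumericMatrix(fixed); moving <- asNumericMatrix(moving)
  if (nrow(fixed) < 3L || nrow(fixed) != nrow(moving))
    pmrCountError("need n >= 3 matched point pairs")
  X <- cbind(moving, 1)
  fit <- try(qr.solve(X, fixed), silent = TRUE)
  if (inherits(fit, "try-error"))
    pmrGeometryError("point configuration is degenerate")
  affine2D(rbind(t(fit), c(0, 0, 1)))
}

#' Run the coarse landmark-based registration
#'
#' @param fixed,moving [Image2D] reference and floating images.
#' @param fixedLm,movingLm [LandmarkTriplet] of corresponding valve points.
#' @return a [BasicResult] with the solved transform, the moving image
#'   resampled into fixed space (bicubic), the validity mask, and the
#'   maximum landmark mapping residual in px.
#' @export
runBasic <- function(fixed, moving, fixedLm, movingLm) {
  t <- solveAffineFromLandmarks(fixedLm, movingLm)
  mapped <- applyTransform(t, landmarkPoints(movingLm))
  residual <- max(sqrt(rowSums((mapped - landmarkPoints(fixedLm))^2)))
  r <- resampleImage(moving, t, outShape = dim(fixed), interp = "cubic",
                     pixelSize = pixelSize(fixed))
  new("BasicResult", tBasic = t, resampled = r$image, valid = r$valid,
      residual = residual)
}
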