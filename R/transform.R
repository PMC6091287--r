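## Transform parameterization for the optimizer.
##
## An affine map moving -> fixed is parameterized about the image centers
## c_m (moving) and c_f (fixed):
##
##   x_f = R(theta) U (x_m - c_m) + c_f + (tx, ty)
##
## with U upper-triangular [[sx, k], [0, sy]] for the "affine6" model
## (tx, ty, theta, sx, sy, k) and U = s I for "rigid_scale4"
## (tx, ty, theta, s). Centering decouples rotation from translation, which
## keeps Powell's per-parameter line searches well conditioned. Parameters
## are scaled so one unit of each moves image content by about one pixel:
## translations in px, angle in radians x 100, scales and shear x 100.

paramScale <- function(model) {
  switch(model,
         affine6      = c(1, 1, 100, 100, 100, 100),
         rigid_scale4 = c(1, 1, 100, 100),
         pmrInputError(sprintf("unknown transform model '%s'", model)))
}

imageCenter <- function(shape) c((shape[2] - 1) / 2, (shape[1] - 1) / 2)

rotationMatrix2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

## params (unscaled) -> Affine2D
paramsToTransform <- function(p, model, centerFixed, centerMoving) {
  if (model == "affine6") {
    A <- rotationMatrix2(p[3]) %*% matrix(c(p[4], 0, p[6], p[5]), 2, 2)
    tr <- p[1:2]
  } else {
    A <- p[4] * rotationMatrix2(p[3])
    tr <- p[1:2]
  }
  b <- centerFixed + tr - as.vector(A %*% centerMoving)
  affine2D(rbind(cbind(A, b), c(0, 0, 1)))
}

## Affine2D -> params (unscaled). For rigid_scale4 the affine part is
## projected onto the nearest rotation + isotropic scale.
transformToParams <- function(t, model, centerFixed, centerMoving) {
  m <- transformMatrix(t)
  A <- m[1:2, 1:2]
  b <- m[1:2, 3]
  tr <- b - centerFixed + as.vector(A %*% centerMoving)
  theta <- atan2(A[2, 1], A[1, 1])
  if (model == "affine6") {
    U <- rotationMatrix2(-theta) %*% A
    c(tr, theta, U[1, 1], U[2, 2], U[1, 2])
  } else {
    s <- sqrt(abs(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]))
    c(tr, theta, s)
  }
}

#' Invert a planar affine transform
#'
#' @param t an [Affine2D].
#' @return the inverse [Affine2D] (fixed -> moving coordinates).
#' @export
invertTransform <- function(t) affine2D(solve(transformMatrix(t)))

#' Compose two transforms
#'
#' Returns the transform applying `b` first, then `a`.
#'
#' @param a,b [Affine2D] objects.
#' @return an [Affine2D] equal to `a %*% b`.
#' @export
composeTransforms <- function(a, b) {
  affine2D(transformMatrix(a) %*% transformMatrix(b))
}
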