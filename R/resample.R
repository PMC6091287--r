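## Pull-based affine resampling with a companion validity mask.
##
## The transform maps moving -> fixed coordinates, so each output (fixed)
## pixel center (x, y) pulls the moving intensity at T^{-1}(x, y). Pixels
## whose source falls outside the moving footprint are filled with 0 and
## flagged invalid so similarity metrics can exclude them.

#' Resample an image through an affine transform
#'
#' @param moving an [Image2D] (or matrix) in moving-image space.
#' @param t an [Affine2D] mapping moving to fixed coordinates.
#' @param outShape output `(h, w)`; defaults to the moving image's shape.
#' @param interp `"cubic"` (Catmull-Rom bicubic, a = -0.5, the common
#'   imaging default), `"linear"` or `"nearest"`.
#' @param pixelSize spacing for the output image; defaults to the input's
#'   when `moving` is an [Image2D].
#' @return a list with `image` (an [Image2D]; negative cubic overshoot is
#'   clamped to 0) and `valid` (a [Mask2D] of pixels whose source lies
#'   inside the moving footprint).
#' @export
resampleImage <- function(moving, t, outShape = NULL,
                          interp = c("cubic", "linear", "nearest"),
                          pixelSize = NULL) {
  interp <- match.arg(interp)
  P <- asPixelMatrix(moving)
  if (is.null(outShape)) outShape <- dim(P)
  if (is.null(pixelSize))
    pixelSize <- if (is(moving, "Image2D")) moving@pixelSize else c(1, 1)
  ti <- try(solve(transformMatrix(t)), silent = TRUE)
  if (inherits(ti, "try-error"))
    pmrGeometryError("transform is not invertible")
  h <- as.integer(outShape[1]); w <- as.integer(outShape[2])
  ## output pixel centers, column-major to match matrix(vec, h, w)
  gx <- rep(0:(w - 1), each = h)
  gy <- rep.int(0:(h - 1), w)
  sx <- ti[1, 1] * gx + ti[1, 2] * gy + ti[1, 3]
  sy <- ti[2, 1] * gx + ti[2, 2] * gy + ti[2, 3]
  out <- interpolateAt(P, sx, sy, interp)
  list(image = image2D(matrix(out$values, h, w), pixelSize = pixelSize),
       valid = mask2D(matrix(out$valid, h, w)))
}

## Scattered interpolation of matrix P at 0-based coordinates (sx, sy).
## Returns values (0 outside the footprint, negatives clamped to 0) and a
## validity flag per point.
interpolateAt <- function(P, sx, sy, interp) {
  hm <- nrow(P); wm <- ncol(P)
  eps <- 1e-9  # tolerate round-off on the footprint edge
  valid <- sx >= -eps & sx <= wm - 1 + eps & sy >= -eps & sy <= hm - 1 + eps
  vals <- numeric(length(sx))
  if (any(valid)) {
    vx <- pmin(pmax(sx[valid], 0), wm - 1)
    vy <- pmin(pmax(sy[valid], 0), hm - 1)
    vals[valid] <- switch(interp,
      nearest = interpNearest(P, vx, vy),
      linear  = interpBilinear(P, vx, vy),
      cubic   = interpBicubic(P, vx, vy))
  }
  list(values = pmax(vals, 0), valid = valid)
}

interpNearest <- function(P, x, y) {
  h <- nrow(P)
  xi <- pmin(round(x), ncol(P) - 1)
  yi <- pmin(round(y), h - 1)
  P[xi * h + yi + 1]
}

interpBilinear <- function(P, x, y) {
  h <- nrow(P); w <- ncol(P)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- x0 * h + y0 + 1
  v00 <- P[i00];     v10 <- P[i00 + h]
  v01 <- P[i00 + 1]; v11 <- P[i00 + h + 1]
  (1 - fx) * ((1 - fy) * v00 + fy * v01) + fx * ((1 - fy) * v10 + fy * v11)
}

## Catmull-Rom cubic convolution weights, kernel parameter a = -0.5.
cubicWeights <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  list(wm1 = -0.5 * f + f2 - 0.5 * f3,
       w0  = 1 - 2.5 * f2 + 1.5 * f3,
       w1  = 0.5 * f + 2 * f2 - 1.5 * f3,
       w2  = -0.5 * f2 + 0.5 * f3)
}

interpBicubic <- function(P, x, y) {
  h <- nrow(P); w <- ncol(P)
  x0 <- floor(x); y0 <- floor(y)
  wx <- cubicWeights(x - x0); wy <- cubicWeights(y - y0)
  wxl <- list(wx$wm1, wx$w0, wx$w1, wx$w2)
  wyl <- list(wy$wm1, wy$w0, wy$w1, wy$w2)
  acc <- numeric(length(x))
  for (i in 1:4) {       # column offset i-2
    xi <- pmin(pmax(x0 + (i - 2), 0), w - 1)  # clamp border neighbors
    base <- xi * h
    for (j in 1:4) {     # row offset j-2
      yi <- pmin(pmax(y0 + (j - 2), 0), h - 1)
      acc <- acc + wxl[[i]] * wyl[[j]] * P[base + yi + 1]
    }
  }
  acc
}

#' Warp a binary mask through an affine transform
#'
#' Nearest-neighbor warping (equivalently, bilinear with a 0.5 threshold on
#' the indicator), intersected with the footprint validity mask.
#'
#' @param mask a [Mask2D] (or logical matrix) in moving space.
#' @param t an [Affine2D] mapping moving to fixed coordinates.
#' @param outShape output `(h, w)`.
#' @return a [Mask2D] in fixed space.
#' @export
warpMask <- function(mask, t, outShape) {
  b <- asMaskMatrix(mask)
  r <- resampleImage(b * 1.0, t, outShape = outShape, interp = "nearest")
  mask2D(pixels(r$image) > 0.5 & maskBits(r$valid))
}
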