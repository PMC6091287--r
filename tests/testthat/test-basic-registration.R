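# Coarse stage: exact 3-point affine solve and pull-based resampling.

test_that("landmark solve handles identity, translation and a known affine", {
  lm <- landmarkTriplet(rbind(c(10, 10), c(50, 20), c(30, 60)))
  expect_equal(transformMatrix(solveAffineFromLandmarks(lm, lm)), diag(3))

  mv <- landmarkTriplet(rbind(c(0, 0), c(10, 0), c(0, 10)))
  fx <- landmarkTriplet(landmarkPoints(mv) + rep(c(5, -3), each = 3))
  expect_equal(transformMatrix(solveAffineFromLandmarks(fx, mv)),
               rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1)))

  A <- affine2D(rbind(c(1.1, 0.2, 5), c(-0.1, 0.95, -3)))
  mv2 <- landmarkTriplet(rbind(c(0, 0), c(40, 0), c(0, 40)))
  fx2 <- landmarkTriplet(applyTransform(A, landmarkPoints(mv2)))
  expect_lt(max(abs(transformMatrix(solveAffineFromLandmarks(fx2, mv2)) -
                    transformMatrix(A))), 1e-9)
})

test_that("solver recovers random generating affines (seeded property)", {
  set.seed(42)
  for (i in 1:200) {
    A <- randomAffine()
    mv <- randomTriplet()
    fx <- landmarkTriplet(applyTransform(A, landmarkPoints(mv)))
    got <- solveAffineFromLandmarks(fx, mv)
    expect_lt(max(abs(transformMatrix(got) - transformMatrix(A))), 1e-7)
  }
})

test_that("degenerate landmark configurations are rejected", {
  # repeated points span zero area and are caught at construction
  expect_error(landmarkTriplet(rbind(c(10, 10), c(10, 10), c(30, 60))),
               class = "pmr_geometry_error")
  expect_error(landmarkTriplet(rbind(c(10, 10), c(50, 20), c(50, 20))),
               class = "pmr_geometry_error")
})

test_that("least-squares extension matches the exact solve at n = 3", {
  set.seed(7)
  A <- randomAffine()
  mv <- randomTriplet()
  fx <- applyTransform(A, landmarkPoints(mv))
  ls <- solveAffineLeastSquares(fx, landmarkPoints(mv))
  expect_lt(max(abs(transformMatrix(ls) - transformMatrix(A))), 1e-7)
  # and recovers exactly from 6 noiseless correspondences
  pts <- cbind(runif(6, 0, 80), runif(6, 0, 80))
  ls6 <- solveAffineLeastSquares(applyTransform(A, pts), pts)
  expect_lt(max(abs(transformMatrix(ls6) - transformMatrix(A))), 1e-7)
})

test_that("resampling is exact at pixel centers under identity and shifts", {
  img <- makeSmoothImage(16, 20)
  r <- resampleImage(img, identityTransform())
  expect_equal(pixels(r$image), img, tolerance = 1e-12)
  expect_true(all(maskBits(r$valid)))

  # integer translation of a constant image: constant inside, 0 in the band
  const <- matrix(100, 16, 20)
  shift <- affine2D(rbind(c(1, 0, 5), c(0, 1, -3)))
  r2 <- resampleImage(const, shift, interp = "cubic")
  v <- maskBits(r2$valid)
  expect_true(all(pixels(r2$image)[v] == 100))
  expect_true(all(pixels(r2$image)[!v] == 0))
  # valid region = columns x >= 5, rows y <= 12 (source in bounds)
  expect_equal(unname(which(v, arr.ind = TRUE)[, 2] >= 6), rep(TRUE, sum(v)))
  expect_equal(sum(v), (20 - 5) * (16 - 3))
})

test_that("90-degree rotation equals the index-permutation oracle", {
  set.seed(1)
  P <- matrix(runif(64, 0, 255), 8, 8)
  c0 <- 3.5  # center of an 8 x 8 grid
  A <- rbind(c(0, -1), c(1, 0))
  b <- c(c0, c0) - A %*% c(c0, c0)
  rot <- affine2D(rbind(cbind(A, b), c(0, 0, 1)))
  r <- resampleImage(P, rot, interp = "cubic")
  expected <- matrix(0, 8, 8)
  for (x in 0:7) for (y in 0:7) {
    s <- solve(transformMatrix(rot)) %*% c(x, y, 1)
    expected[y + 1, x + 1] <- P[round(s[2]) + 1, round(s[1]) + 1]
  }
  expect_true(all(maskBits(r$valid)))
  expect_equal(pixels(r$image), expected, tolerance = 1e-9)
})

test_that("bilinear resampling matches a dense loop oracle", {
  set.seed(3)
  P <- makeSmoothImage(12, 14)
  tr <- randomAffine()
  r <- resampleImage(P, tr, outShape = c(12, 14), interp = "linear")
  o <- oracleBilinearWarp(P, transformMatrix(tr), 12, 14)
  expect_identical(maskBits(r$valid), o$valid)
  expect_equal(pixels(r$image)[o$valid], o$values[o$valid], tolerance = 1e-9)
})

test_that("warp then inverse warp returns the image on the doubly-valid region", {
  set.seed(5)
  img <- makeSmoothImage(48, 48)
  for (i in 1:3) {
    tr <- randomAffine()
    f <- resampleImage(img, tr, outShape = c(48, 48), interp = "cubic")
    back <- resampleImage(f$image, invertTransform(tr), outShape = c(48, 48),
                          interp = "cubic")
    both <- maskBits(back$valid) &
      maskBits(warpMask(f$valid, invertTransform(tr), c(48, 48)))
    # erode the region: pixels whose cubic stencil touched invalid samples
    interior <- both
    interior[c(1:3, 46:48), ] <- FALSE
    interior[, c(1:3, 46:48)] <- FALSE
    expect_lt(max(abs(pixels(back$image)[interior] - img[interior])), 2)
  }
})

test_that("runBasic recovers the phantom ground truth from exact landmarks", {
  pair <- makePhantomPair(11, smallPhantomParams())
  res <- runBasic(pair@fixed, pair@moving, pair@fixedLm, pair@movingLm)
  expect_lt(res@residual, 1e-6)
  expect_lt(max(abs(transformMatrix(res@tBasic) -
                    transformMatrix(pair@tTrue))), 1e-6)
})

test_that("self-registration with identical landmarks reproduces the image", {
  img <- image2D(makeSmoothImage(32, 32))
  lm <- landmarkTriplet(rbind(c(5, 5), c(25, 8), c(12, 26)))
  res <- runBasic(img, img, lm, lm)
  expect_lt(res@residual, 1e-9)
  expect_equal(pixels(res@resampled), pixels(img), tolerance = 1e-9)
})

test_that("perturbed landmarks keep residual zero but bias the transform", {
  pair <- makePhantomPair(12, smallPhantomParams())
  shifted <- landmarkTriplet(landmarkPoints(pair@movingLm) + 0.5)
  res <- runBasic(pair@fixed, pair@moving, pair@fixedLm, shifted)
  expect_lt(res@residual, 1e-6)  # 3 points always fit exactly
  expect_gt(max(abs(transformMatrix(res@tBasic) -
                    transformMatrix(pair@tTrue))), 1e-3)
})
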