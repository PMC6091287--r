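# Normalized mutual information and Powell's direction-set optimizer.

test_that("NMI hits its analytic limits", {
  A <- makeSmoothImage(40, 40)
  expect_equal(nmi(A, A), 2, tolerance = 1e-9)

  set.seed(31)
  u1 <- matrix(runif(320 * 320, 0, 255), 320, 320)
  u2 <- matrix(runif(320 * 320, 0, 255), 320, 320)
  expect_equal(nmi(u1, u2, bins = 64), 1, tolerance = 0.02)

  expect_error(nmi(matrix(5, 20, 20), A[1:20, 1:20]),
               class = "pmr_degenerate_error")
  expect_error(nmi(A, A[1:20, 1:20]), class = "pmr_shape_error")
})

test_that("NMI agrees with a brute-force joint-count oracle", {
  set.seed(32)
  for (i in 1:10) {
    a <- matrix(runif(256, 0, 255), 16, 16)
    b <- 0.5 * a + 0.5 * matrix(runif(256, 0, 255), 16, 16)
    expect_equal(nmi(a, b, bins = 16), oracleNMI(a, b, 16), tolerance = 1e-12)
  }
})

test_that("the validity mask excludes fill pixels from the histogram", {
  set.seed(33)
  a <- matrix(runif(400, 0, 255), 20, 20)
  b <- a + matrix(rnorm(400, 0, 5), 20, 20)
  v <- matrix(TRUE, 20, 20); v[, 1:8] <- FALSE
  bMasked <- b; bMasked[, 1:8] <- 0  # fill values as left by warping
  expect_equal(nmi(a, bMasked, bins = 16, valid = v),
               oracleNMI(a[v], bMasked[v], 16), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(nmi(a, bMasked, bins = 16, valid = v),
                                nmi(a, bMasked, bins = 16))))
  expect_error(nmi(a, b, valid = matrix(FALSE, 20, 20)),
               class = "pmr_input_error")
})

test_that("the direction-set optimizer minimizes a rotated quadratic", {
  H <- rbind(c(4, 1, 0), c(1, 3, -1), c(0, -1, 2))   # positive definite
  x0 <- c(2, -1, 3)
  fn <- function(p) as.numeric(t(p - x0) %*% H %*% (p - x0))
  out <- probmapreg:::powellOptim(fn, c(0, 0, 0), xtol = 1e-6)
  expect_lt(max(abs(out$par - x0)), 1e-3)
  expect_true(all(diff(out$trace) <= 1e-12))  # accepted points never worsen
})

test_that("self-registration starts and stays at the global optimum", {
  pair <- makePhantomPair(14, smallPhantomParams())
  pm <- makeProbabilityMap(pair@fixed, pair@fixedMask, 80)
  out <- powellRegister(pm, pm, identityTransform())
  expect_equal(out$nmiFinal, 2, tolerance = 1e-6)
  expect_lt(maxDisplacement(out$transform, identityTransform(), dim(pm)), 0.5)
})

test_that("a small translation offset is recovered by the optimizer", {
  # a smooth self-registration target has a sharp NMI optimum, so the
  # recovered offset is subpixel-exact
  img <- makeSmoothImage(160, 160) +
    pixels(makePhantomPair(15, smallPhantomParams())@fixed)
  tInit <- affine2D(rbind(c(1, 0, 3), c(0, 1, 2)))
  out <- powellRegister(img, img, tInit)
  expect_lt(maxDisplacement(out$transform, identityTransform(), dim(img)), 0.1)
  expect_gte(out$nmiFinal, out$nmiInitial)
  expect_true(all(diff(out$trace) >= -1e-12))  # NMI trace non-decreasing
})

test_that("registration results dominate their warm start", {
  pair <- makePhantomPair(16, smallPhantomParams())
  mlm <- perturbLandmarks(pair@movingLm, 2, seed = 5, shape = dim(pair@moving))
  res <- registerMultimodal(pair@fixed, pair@moving, pair@fixedMask,
                            pair@movingMask, pair@fixedLm, mlm)
  expect_gte(res@nmiFinal, res@nmiInitial - 1e-9)
  expect_true(all(diff(res@trace) >= -1e-12))
  ev <- evaluateRun(res, pair@movingMask, pair@tTrue)
  expect_gt(ev@dice, 0.95)
})

test_that("the recovered transform is robust to the histogram bin count", {
  # full-size noise-free phantom: the probability maps are exact
  # indicators, so bin placement only touches interpolated edge values
  pair <- makePhantomPair(17, phantomParams(speckleStrength = 0,
                                            gaussianNoiseSd = 0))
  mlm <- perturbLandmarks(pair@movingLm, 1, seed = 6, shape = dim(pair@moving))
  run <- function(bins) registerMultimodal(
    pair@fixed, pair@moving, pair@fixedMask, pair@movingMask,
    pair@fixedLm, mlm, registrationConfig(nmiBins = bins))@tFinal
  expect_lt(maxDisplacement(run(32L), run(128L), dim(pair@fixed)), 0.5)
})

test_that("mismatched or empty masks are rejected", {
  pair <- makePhantomPair(18, smallPhantomParams())
  badMask <- mask2D(matrix(TRUE, 10, 10))
  expect_error(registerMultimodal(pair@fixed, pair@moving, badMask,
                                  pair@movingMask, pair@fixedLm, pair@movingLm),
               class = "pmr_input_error")
  empty <- mask2D(matrix(FALSE, nrow(maskBits(pair@fixedMask)),
                         ncol(maskBits(pair@fixedMask))))
  expect_error(registerMultimodal(pair@fixed, pair@moving, empty,
                                  pair@movingMask, pair@fixedLm, pair@movingLm),
               class = "pmr_input_error")
})

test_that("rigid-plus-scale model still aligns a rigidly displaced phantom", {
  pair <- makePhantomPair(19, smallPhantomParams(shearRange = 0,
                                                 scaleRange = c(1, 1)))
  mlm <- perturbLandmarks(pair@movingLm, 1, seed = 8, shape = dim(pair@moving))
  res <- registerMultimodal(pair@fixed, pair@moving, pair@fixedMask,
                            pair@movingMask, pair@fixedLm, mlm,
                            registrationConfig(transformModel = "rigid_scale4"))
  ev <- evaluateRun(res, pair@movingMask, pair@tTrue)
  expect_gt(ev@dice, 0.95)
})
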