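# Domain types: validity rules, coordinate convention, file round trips.

test_that("Image2D enforces its invariants", {
  expect_s4_class(image2D(matrix(0, 8, 8)), "Image2D")
  expect_error(image2D(matrix(0, 4, 20)), "8 x 8")
  expect_error(image2D(matrix(NaN, 10, 10)), "finite")
  expect_error(image2D(matrix(0, 10, 10), pixelSize = c(1, -1)), "positive")
  img <- image2D(matrix(1:100 / 1, 10, 10), pixelSize = c(0.5, 0.25))
  expect_identical(dim(img), c(10L, 10L))
  expect_identical(pixelSize(img), c(0.5, 0.25))
})

test_that("landmark triplets reject bad geometry and bad counts", {
  good <- landmarkTriplet(rbind(c(10, 10), c(50, 20), c(30, 60)),
                          shape = c(100, 100))
  expect_s4_class(good, "LandmarkTriplet")
  expect_error(landmarkTriplet(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "pmr_geometry_error")
  expect_error(landmarkTriplet(rbind(c(10, 10), c(50, 20))),
               class = "pmr_count_error")
  expect_error(landmarkTriplet(rbind(c(10, 10), c(50, 20), c(30, 120)),
                               shape = c(100, 100)),
               class = "pmr_bounds_error")
})

test_that("affine transforms enforce invertibility and homogeneous form", {
  expect_error(affine2D(rbind(c(1, 2, 0), c(2, 4, 0), c(0, 0, 1))),
               class = "pmr_geometry_error")
  t23 <- affine2D(rbind(c(1, 0, 5), c(0, 1, -3)))
  expect_equal(transformMatrix(t23)[3, ], c(0, 0, 1))
  p <- applyTransform(t23, c(2, 2))
  expect_equal(as.vector(p), c(7, -1))
})

test_that("coordinate convention: (x = col, y = row), 0-based, pixel centers", {
  # a pure +x translation moves content along matrix columns
  img <- matrix(0, 8, 8); img[3, 2] <- 100  # point at x = 1, y = 2
  shift <- affine2D(rbind(c(1, 0, 3), c(0, 1, 0)))
  out <- pixels(resampleImage(img, shift, interp = "nearest")$image)
  expect_equal(out[3, 5], 100)  # now at x = 4, y = 2
  expect_equal(sum(out), 100)
})

test_that("image and mask files round trip", {
  d <- withr::local_tempdir()
  m <- matrix(as.double(sample.int(256, 240, replace = TRUE) - 1), 12, 20)
  f <- file.path(d, "img.png")
  writeImage2D(image2D(m), f)
  back <- readImage2D(f)
  expect_equal(pixels(back), m)           # 8-bit data round trip exactly
  expect_equal(pixelSize(back), c(1, 1))
  expect_equal(pixelSize(readImage2D(f, modality = "CT")), c(0.32, 0.32))
  expect_equal(pixelSize(readImage2D(f, modality = "TEE")), c(0.224, 0.224))

  ft <- file.path(d, "img.tif")   # float TIFF keeps fractional intensities
  writeImage2D(image2D(m / 2 + 0.25), ft)
  expect_equal(pixels(readImage2D(ft)), m / 2 + 0.25, tolerance = 1e-6)

  mk <- mask2D(matrix(runif(240) > 0.6, 12, 20))
  fm <- file.path(d, "mask.png")
  writeMask2D(mk, fm)
  expect_identical(maskBits(readMask2D(fm)), maskBits(mk))
})

test_that("deep rasters are rescaled to [0, 255] with a warning", {
  d <- withr::local_tempdir()
  f <- file.path(d, "deep.tif")
  tiff::writeTIFF(matrix(runif(100), 10, 10), f, bits.per.sample = 16L)
  expect_warning(img <- readImage2D(f), "8 bits")
  expect_lte(max(pixels(img)), 255)
})

test_that("genuine color images are rejected, gray-as-RGB accepted", {
  d <- withr::local_tempdir()
  g <- matrix(runif(64), 8, 8)
  rgbGray <- array(rep(g, 3), c(8, 8, 3))
  f1 <- file.path(d, "gray3.png")
  png::writePNG(rgbGray, f1)
  expect_equal(pixels(readImage2D(f1)), g * 255, tolerance = 0.5)
  color <- rgbGray; color[, , 2] <- 1 - color[, , 2]
  f2 <- file.path(d, "color.png")
  png::writePNG(color, f2)
  expect_error(readImage2D(f2), class = "pmr_format_error")
})

test_that("landmark CSV IO validates count, bounds and geometry", {
  d <- withr::local_tempdir()
  img <- image2D(matrix(0, 100, 100))
  f <- file.path(d, "lm.csv")

  writeLines("x,y\n10,10\n50,20\n30,60", f)
  lm <- readLandmarks(f, img)
  expect_equal(unname(landmarkPoints(lm)), rbind(c(10, 10), c(50, 20), c(30, 60)))

  writeLines("x,y\n0,0\n1,1\n2,2", f)
  expect_error(readLandmarks(f, img), class = "pmr_geometry_error")
  writeLines("x,y\n10,10\n50,20", f)
  expect_error(readLandmarks(f, img), class = "pmr_count_error")
  writeLines("x,y\n10,10\n50,20\n30,600", f)
  expect_error(readLandmarks(f, img), class = "pmr_bounds_error")

  lm2 <- landmarkTriplet(rbind(c(1.25, 2.5), c(10, 3), c(4, 9)))
  writeLandmarks(lm2, f)
  expect_equal(landmarkPoints(readLandmarks(f)), landmarkPoints(lm2))
})

test_that("transform text files round trip to full precision", {
  d <- withr::local_tempdir()
  f <- file.path(d, "t.txt")
  writeTransform(identityTransform(), f)
  expect_equal(transformMatrix(readTransform(f)), diag(3))

  tr <- affine2D(rbind(c(1, 0, 5), c(0, 1, -3)))
  writeTransform(tr, f)
  expect_equal(transformMatrix(readTransform(f)), transformMatrix(tr),
               tolerance = 1e-12)

  tw <- affine2D(rbind(c(1.1, 0.2, 5.123456789012345),
                       c(-0.1, 0.95, -3.987654321098765)))
  writeTransform(tw, f)
  expect_lt(max(abs(transformMatrix(readTransform(f)) - transformMatrix(tw))),
            1e-12)

  writeLines(c("1 0 0", "2 0 0", "0 0 1"), f)   # singular 2x2 block
  expect_error(readTransform(f), class = "pmr_geometry_error")
  writeLines("not a matrix", f)
  expect_error(readTransform(f), class = "pmr_format_error")
})
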