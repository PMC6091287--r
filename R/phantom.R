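## Synthetic multimodal phantom: a pseudo-CT / pseudo-TEE pair of the same
## "heart" scene related by a known affine transform, with co-generated
## foreground masks and valve landmark triplets. The scene is analytic
## (overlapping ellipse "chambers" plus a bright thin "valve" segment over
## a dark background), so the moving image can be rendered exactly at
## transformed coordinates with no interpolation error. The modality gap is
## emulated by a monotone gamma-like intensity remap with a level inversion
## of one chamber, multiplicative unit-mean Rayleigh-derived speckle, and a
## fan/sector ultrasound footprint on the moving image.

#' Phantom generator settings constructor
#'
#' Defaults define the benchmark's study conditions: a 320 x 320 fixed
#' canvas (desk-scale stand-in for 1024 x 1024 clinical CT) against a
#' 240 x 320 moving canvas, ground-truth deformations up to 10 degrees
#' rotation, 20 px translation, 0.9-1.1 scaling and 0.05 shear (a
#' large-deformation regime for 2D cardiac slices), partially developed
#' speckle (strength 0.5) and mild CT noise (sd 2 gray levels).
#'
#' @param canvas fixed-image `(h, w)`.
#' @param movingCanvas moving-image `(h, w)`.
#' @param rotationRange max |rotation| in degrees.
#' @param translationRange max |translation| per axis in px.
#' @param scaleRange interval for the two anisotropic scale factors.
#' @param shearRange max |shear| coefficient.
#' @param speckleStrength blending weight in [0, 1] of unit-mean Rayleigh
#'   speckle on the moving image (1 = fully developed).
#' @param gaussianNoiseSd additive noise sd on the fixed image, gray levels.
#' @param fanMask apply the fan/sector footprint to the moving image.
#' @param intensityRemap `"echo_like"` (chamber levels collapse
#'   many-to-one onto near-anechoic values while the valve stays bright —
#'   makes raw-intensity similarity a poor objective, as on real CT/TEE
#'   pairs) or `"identity"`.
#' @return a [PhantomParams].
#' @export
phantomParams <- function(canvas = c(320L, 320L),
                          movingCanvas = c(240L, 320L),
                          rotationRange = 10, translationRange = 20,
                          scaleRange = c(0.9, 1.1), shearRange = 0.05,
                          speckleStrength = 0.5, gaussianNoiseSd = 2,
                          fanMask = TRUE,
                          intensityRemap = c("echo_like", "identity")) {
  new("PhantomParams", canvas = as.integer(canvas),
      movingCanvas = as.integer(movingCanvas),
      rotationRange = as.numeric(rotationRange),
      translationRange = as.numeric(translationRange),
      scaleRange = as.numeric(scaleRange),
      shearRange = as.numeric(shearRange),
      speckleStrength = as.numeric(speckleStrength),
      gaussianNoiseSd = as.numeric(gaussianNoiseSd),
      fanMask = isTRUE(fanMask),
      intensityRemap = match.arg(intensityRemap))
}

## Evaluate expr with a temporary RNG state; fully deterministic in `seed`
## and side-effect free for the caller's RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic multimodal pair with known ground truth
#'
#' Deterministic in `(seed, params)`: the same inputs reproduce the pair
#' bit-for-bit. The ground-truth transform maps moving to fixed
#' coordinates; the moving landmarks are its exact inverse images of the
#' fixed ones (valve endpoints and midpoint), before any perturbation.
#'
#' @param seed integer seed.
#' @param params a [PhantomParams].
#' @return a [PhantomPair]. Both images carry 1 mm isotropic pixel spacing.
#' @export
makePhantomPair <- function(seed = 0L, params = phantomParams()) {
  validObject(params)
  seed <- as.integer(seed)
  withSeed(seed, {
    hF <- params@canvas[1]; wF <- params@canvas[2]
    hM <- params@movingCanvas[1]; wM <- params@movingCanvas[2]
    geom <- drawSceneGeometry(hF, wF)

    ## ground-truth transform; re-drawn (deterministically) if it pushes a
    ## valve landmark outside either canvas
    fixedPts <- geom$valvePoints
    for (try in 1:50) {
      tTrue <- drawTransform(params, c(hF, wF), c(hM, wM))
      movingPts <- applyTransform(invertTransform(tTrue), fixedPts)
      okF <- all(fixedPts[, 1] >= 2 & fixedPts[, 1] <= wF - 3 &
                 fixedPts[, 2] >= 2 & fixedPts[, 2] <= hF - 3)
      okM <- all(movingPts[, 1] >= 2 & movingPts[, 1] <= wM - 3 &
                 movingPts[, 2] >= 2 & movingPts[, 2] <= hM - 3)
      if (okF && okM) break
      if (try == 50) pmrGeometryError(
        "could not place landmarks inside both canvases; widen the canvases or narrow the transform ranges")
    }

    ## fixed pseudo-CT: render labels on the fixed grid
    gxF <- rep(0:(wF - 1), each = hF)
    gyF <- rep.int(0:(hF - 1), wF)
    labF <- labelAt(gxF, gyF, geom)
    ctLevels <- geom$ctLevels
    pixF <- ctLevels[labF + 1L] +
      stats::rnorm(hF * wF, 0, params@gaussianNoiseSd)
    pixF <- round(pmin(pmax(pixF, 0), 255))
    fixedImg <- image2D(matrix(pixF, hF, wF))
    fixedMask <- mask2D(matrix(labF > 0L, hF, wF))

    ## moving pseudo-TEE: sample labels at ground-truth-mapped coordinates
    m <- transformMatrix(tTrue)
    gxM <- rep(0:(wM - 1), each = hM)
    gyM <- rep.int(0:(hM - 1), wM)
    fx <- m[1, 1] * gxM + m[1, 2] * gyM + m[1, 3]
    fy <- m[2, 1] * gxM + m[2, 2] * gyM + m[2, 3]
    labM <- labelAt(fx, fy, geom)
    teeLevels <- if (params@intensityRemap == "identity") ctLevels
                 else remapLevels(ctLevels)
    pixM <- teeLevels[labM + 1L]
    if (params@speckleStrength > 0) {
      ray <- sqrt(-4 * log(stats::runif(hM * wM)) / pi)  # unit-mean Rayleigh
      pixM <- pixM * (1 + params@speckleStrength * (ray - 1))
    }
    maskM <- labM > 0L
    if (params@fanMask) {
      fan <- fanFootprint(gxM, gyM, hM, wM)
      pixM[!fan] <- 0
      maskM <- maskM & fan
    }
    pixM <- round(pmin(pmax(pixM, 0), 255))
    movingImg <- image2D(matrix(pixM, hM, wM))
    movingMask <- mask2D(matrix(maskM, hM, wM))
    if (!any(maskBits(movingMask)))
      pmrGeometryError("moving-image foreground fell outside the fan footprint")

    new("PhantomPair",
        fixed = fixedImg, moving = movingImg,
        fixedMask = fixedMask, movingMask = movingMask,
        fixedLm = landmarkTriplet(fixedPts, shape = c(hF, wF)),
        movingLm = landmarkTriplet(movingPts, shape = c(hM, wM)),
        tTrue = tTrue, seed = seed, params = params)
  })
}

#' Perturb a landmark triplet with Gaussian clicking error
#'
#' Adds i.i.d. Gaussian offsets to each coordinate, resampling (up to 100
#' times) if the result is collinear or, when `shape` is given, out of
#' bounds.
#'
#' @param lm a [LandmarkTriplet].
#' @param sd offset standard deviation in px.
#' @param seed integer seed.
#' @param shape optional image `(h, w)` bound.
#' @return a perturbed [LandmarkTriplet]; `sd = 0` returns `lm` unchanged.
#' @export
perturbLandmarks <- function(lm, sd, seed = 0L, shape = NULL) {
  if (sd < 0) pmrInputError("sd must be >= 0")
  if (sd == 0) return(lm)
  p <- landmarkPoints(lm)
  withSeed(as.integer(seed), {
    for (i in 1:100) {
      cand <- p + matrix(stats::rnorm(6, 0, sd), 3, 2)
      ok <- abs(signedDoubledArea(cand)) > 1e-6
      if (ok && !is.null(shape)) {
        ok <- all(cand[, 1] >= 0 & cand[, 1] <= shape[2] - 1 &
                  cand[, 2] >= 0 & cand[, 2] <= shape[1] - 1)
      }
      if (ok) return(landmarkTriplet(cand, shape = shape))
    }
    pmrGeometryError("could not produce a valid perturbed triplet in 100 tries")
  })
}

#' Benchmark the two-stage registration on seeded phantoms
#'
#' For each seed: generate a phantom pair, perturb the moving landmarks,
#' run the registration in both modes (probability-map metric and
#' raw-intensity baseline), and evaluate each against the ground-truth
#' transform over the moving-image foreground.
#'
#' @param nSeeds number of phantom seeds (seeds are `seedOffset + 1:nSeeds`).
#' @param params a [PhantomParams].
#' @param cfg a [RegistrationConfig].
#' @param landmarkSd clicking-error sd applied to the moving landmarks, px.
#' @param seedOffset added to every seed (ties the benchmark to an external
#'   master seed).
#' @return a data.frame with one row per seed: Dice, TRE (mm), initial and
#'   final NMI for both modes, plus an `error` column (NA on success;
#'   individual-seed failures are recorded, not fatal).
#' @export
runBenchmark <- function(nSeeds = 10L, params = phantomParams(),
                         cfg = registrationConfig(), landmarkSd = 2,
                         seedOffset = 0L) {
  if (nSeeds < 1L) pmrInputError("nSeeds must be >= 1")
  rows <- lapply(seq_len(nSeeds), function(s) {
    seed <- as.integer(seedOffset + s)
    out <- data.frame(seed = seed, dice_probmap = NA_real_,
                      tre_probmap = NA_real_, dice_intensity = NA_real_,
                      tre_intensity = NA_real_,
                      nmi_initial_probmap = NA_real_,
                      nmi_final_probmap = NA_real_,
                      nmi_initial_intensity = NA_real_,
                      nmi_final_intensity = NA_real_,
                      error = NA_character_)
    tryCatch({
      pair <- makePhantomPair(seed, params)
      pseed <- as.integer((as.numeric(seed) * 1009 + 7) %%
                            .Machine$integer.max)
      mlm <- perturbLandmarks(pair@movingLm, landmarkSd, seed = pseed,
                              shape = dim(pair@moving))
      for (mode in c("probmap", "intensity")) {
        res <- registerMultimodal(pair@fixed, pair@moving,
                                  pair@fixedMask, pair@movingMask,
                                  pair@fixedLm, mlm, cfg, mode = mode)
        ev <- evaluateRun(res, pair@movingMask, pair@tTrue,
                          pixelSize = pixelSize(pair@fixed),
                          reference = "phantom_truth")
        out[[paste0("dice_", mode)]] <- ev@dice
        out[[paste0("tre_", mode)]] <- ev@treRmsMm
        out[[paste0("nmi_initial_", mode)]] <- res@nmiInitial
        out[[paste0("nmi_final_", mode)]] <- res@nmiFinal
      }
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  do.call(rbind, rows)
}

## internal scene machinery -------------------------------------------------

## Seeded scene geometry in fixed-image coordinates: three chamber ellipses
## (painter's order) and a valve capsule whose endpoints/midpoint are the
## landmarks. Sizes scale with the canvas.
drawSceneGeometry <- function(h, w) {
  s <- min(h, w) / 320
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  j <- function(r) stats::runif(1, -r, r)
  ell <- list(
    list(cx = cx - 28 * s + j(8 * s), cy = cy - 20 * s + j(8 * s),
         a = (52 + j(4)) * s, b = (44 + j(4)) * s,
         ang = (20 + j(8)) * pi / 180),
    list(cx = cx + 30 * s + j(8 * s), cy = cy - 24 * s + j(8 * s),
         a = (44 + j(4)) * s, b = (38 + j(4)) * s,
         ang = (-15 + j(8)) * pi / 180),
    list(cx = cx + 2 * s + j(8 * s), cy = cy + 30 * s + j(8 * s),
         a = (58 + j(4)) * s, b = (40 + j(4)) * s,
         ang = (5 + j(8)) * pi / 180))
  e1 <- c(cx + (-30 + j(5)) * s, cy + (6 + j(5)) * s)
  e2 <- c(cx + (26 + j(5)) * s, cy + (10 + j(5)) * s)
  ## third landmark well off the valve chord (as when a point of a second
  ## valve is used): a thin triangle would make the 3-point affine solve
  ## ill-conditioned under clicking error
  d <- e2 - e1
  n <- c(-d[2], d[1]) / sqrt(sum(d * d))
  mid <- (e1 + e2) / 2 + (20 + j(3)) * s * n
  list(ellipses = ell,
       valve = list(p1 = e1, p2 = e2, halfwidth = 2.5 * s),
       valvePoints = rbind(e1, mid, e2),
       ctLevels = c(20, 110, 150, 90, 230))
}

## Vectorized label lookup at continuous coordinates: 0 = background,
## 1..3 = chambers (later ellipses paint over earlier), 4 = valve.
labelAt <- function(x, y, geom) {
  lab <- integer(length(x))
  for (i in seq_along(geom$ellipses)) {
    e <- geom$ellipses[[i]]
    dx <- x - e$cx; dy <- y - e$cy
    u <- cos(e$ang) * dx + sin(e$ang) * dy
    v <- -sin(e$ang) * dx + cos(e$ang) * dy
    lab[(u / e$a)^2 + (v / e$b)^2 <= 1] <- i
  }
  vv <- geom$valve
  d <- vv$p2 - vv$p1
  len2 <- sum(d * d)
  tpar <- pmin(pmax(((x - vv$p1[1]) * d[1] + (y - vv$p1[2]) * d[2]) / len2, 0), 1)
  distx <- x - (vv$p1[1] + tpar * d[1])
  disty <- y - (vv$p1[2] + tpar * d[2])
  lab[distx^2 + disty^2 <= vv$halfwidth^2] <- 4L
  lab
}

## Echo-like intensity remapping: gamma-darkened levels with the
## blood-filled chambers collapsed to near-anechoic values close to the
## background, while the valve stays bright. The collapse is many-to-one:
## structures well separated in CT gray levels become nearly
## indistinguishable in the pseudo-TEE, which is what makes raw-intensity
## mutual information a poor objective on real CT/TEE pairs. (A merely
## monotone or permuted remap would leave histogram-based MI unchanged.)
remapLevels <- function(ctLevels) {
  ## labels:   bg  ch1  ch2  ch3  valve
  ## CT:       20  110  150   90  230
  c(5, 16, 10, 13, 190)
}

drawTransform <- function(params, shapeFixed, shapeMoving) {
  theta <- stats::runif(1, -params@rotationRange, params@rotationRange) * pi / 180
  sx <- stats::runif(1, params@scaleRange[1], params@scaleRange[2])
  sy <- stats::runif(1, params@scaleRange[1], params@scaleRange[2])
  k <- stats::runif(1, -params@shearRange, params@shearRange)
  tx <- stats::runif(1, -params@translationRange, params@translationRange)
  ty <- stats::runif(1, -params@translationRange, params@translationRange)
  paramsToTransform(c(tx, ty, theta, sx, sy, k), "affine6",
                    imageCenter(shapeFixed), imageCenter(shapeMoving))
}

## Fan/sector ultrasound footprint on the moving canvas: apex above the
## top edge, opening downwards.
fanFootprint <- function(gx, gy, h, w) {
  ax <- (w - 1) / 2; ay <- -0.25 * h
  dx <- gx - ax; dy <- gy - ay
  r <- sqrt(dx * dx + dy * dy)
  ang <- atan2(dx, dy)  # 0 = straight down
  abs(ang) <= 48 * pi / 180 & r <= 1.4 * h
}
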