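# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the implementation.

# Per-intensity ROI-membership density by explicit per-intensity counting.
oracleDensity <- function(img, roi) {
  v <- round(as.vector(img))
  r <- as.vector(roi)
  ints <- sort(unique(v))
  probs <- vapply(ints, function(i) sum(r[v == i]) / sum(v == i), numeric(1))
  list(intensities = as.integer(ints), probs = probs)
}

# Studholme NMI by explicit joint-count accumulation over a double loop.
oracleNMI <- function(a, b, bins) {
  a <- as.vector(a); b <- as.vector(b)
  ra <- range(a); rb <- range(b)
  ia <- pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * bins), bins - 1)
  ib <- pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * bins), bins - 1)
  joint <- matrix(0, bins, bins)
  for (k in seq_along(ia))
    joint[ia[k] + 1, ib[k] + 1] <- joint[ia[k] + 1, ib[k] + 1] + 1
  pj <- joint / length(ia)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(rowSums(pj)) + ent(colSums(pj))) / ent(pj)
}

# Dense per-pixel bilinear warp by an explicit loop (pull semantics).
oracleBilinearWarp <- function(P, tmat, h, w) {
  ti <- solve(tmat)
  out <- matrix(0, h, w)
  valid <- matrix(FALSE, h, w)
  for (x in 0:(w - 1)) for (y in 0:(h - 1)) {
    s <- ti %*% c(x, y, 1)
    sx <- s[1]; sy <- s[2]
    if (sx >= 0 && sx <= ncol(P) - 1 && sy >= 0 && sy <= nrow(P) - 1) {
      x0 <- min(floor(sx), ncol(P) - 2); y0 <- min(floor(sy), nrow(P) - 2)
      fx <- sx - x0; fy <- sy - y0
      out[y + 1, x + 1] <-
        (1 - fx) * ((1 - fy) * P[y0 + 1, x0 + 1] + fy * P[y0 + 2, x0 + 1]) +
        fx * ((1 - fy) * P[y0 + 1, x0 + 2] + fy * P[y0 + 2, x0 + 2])
      valid[y + 1, x + 1] <- TRUE
    }
  }
  list(values = out, valid = valid)
}

# Smooth band-limited test image (no discontinuities, good for
# interpolation round trips).
makeSmoothImage <- function(h, w) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  100 + 60 * sin(2 * pi * xs / w) * cos(2 * pi * ys / h) +
    40 * sin(2 * pi * (xs + 2 * ys) / (w + h))
}

# Random well-conditioned affine near the identity.
randomAffine <- function() {
  theta <- runif(1, -0.3, 0.3)
  sx <- runif(1, 0.8, 1.2); sy <- runif(1, 0.8, 1.2)
  k <- runif(1, -0.1, 0.1)
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2) %*%
    matrix(c(sx, 0, k, sy), 2, 2)
  affine2D(rbind(cbind(A, runif(2, -10, 10)), c(0, 0, 1)))
}

# Random non-collinear landmark triplet inside a (h, w) canvas.
randomTriplet <- function(h = 100, w = 100) {
  repeat {
    p <- cbind(runif(3, 5, w - 6), runif(3, 5, h - 6))
    if (abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
            (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) > 1) {
      return(landmarkTriplet(p, shape = c(h, w)))
    }
  }
}

# Desk-scale phantom settings for fast registration tests.
smallPhantomParams <- function(...) {
  phantomParams(canvas = c(160L, 160L), movingCanvas = c(128L, 160L),
                translationRange = 10, ...)
}

# Maximum displacement between two transforms over an (h, w) pixel domain
# (checked at the domain corners; affine displacement is extremal there).
maxDisplacement <- function(ta, tb, shape) {
  corners <- rbind(c(0, 0), c(shape[2] - 1, 0), c(0, shape[1] - 1),
                   c(shape[2] - 1, shape[1] - 1))
  max(sqrt(rowSums((applyTransform(ta, corners) -
                    applyTransform(tb, corners))^2)))
}
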