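test_that("clipped gradient matches analytic derivatives", {
  expect_equal(clippedGradient(seq(10, 1, length.out = 10), 1), rep(0, 10))
  ramp <- clippedGradient(0.5 * (0:19), sampleRate = 2)  # slope 1 per s
  expect_equal(ramp[1:19], rep(1, 19))
  fs <- 50
  tt <- (0:499) / fs
  g <- clippedGradient(sin(tt), fs)
  expect_lt(max(abs(g[1:499] - pmax(0, cos(tt[1:499] + 0.5 / fs)))), 0.03)
  expect_error(clippedGradient(1), "at least 2")
})

test_that("upsampling pairs stimulus and rate on a common 50 Hz grid", {
  cdot <- rep(2, 300)
  up <- upsamplePair(50, 5, cdot, sampleRate = RECORDING_RATE_HZ, onsetS = 0)
  expect_equal(length(up$frameIndex), 500)  # 50 frames x 10
  expect_equal(up$fsUp, 50)
  expect_true(all(up$cdot == 2))            # constant stays constant
  # zero-order hold inverse: every 10th sample returns the frame sequence
  expect_equal(up$frameIndex[seq(1, 500, by = 10)], 1:50)
  # short trace: trimmed with a warning
  expect_warning(
    up2 <- upsamplePair(50, 5, rep(1, 20), onsetS = 0),
    "trimmed")
  expect_gt(up2$dropped, 0)
})

test_that("design features reduce to the raw lagged stimulus for an identity basis", {
  set.seed(2)
  # a basis whose axis matrices are identity recovers X itself
  b <- splineBasis(dims = c(4L, 4L, 4L), knots = c(4L, 4L, 4L))
  b@Sx <- diag(4); b@Sy <- diag(4); b@St <- diag(4)
  nf <- 40
  frames <- array(rbinom(4 * 4 * nf, 1, 0.5) - 0.5, dim = c(4, 4, nf))
  up <- list(frameIndex = seq_len(nf), cdot = numeric(nf), fsUp = 5)
  des <- buildDesign(frames, b, up, lagSamples = 0:3)
  fm <- matrix(frames, nrow = 16)
  t0 <- des$valid[5]
  row <- des$X[5, ]
  for (l in 0:3)
    expect_equal(row[l * 16 + 1:16], fm[, t0 - l])
  # time-shift structure: shifting the stimulus by one lag step shifts blocks
  t1 <- des$valid[6]
  expect_equal(des$X[6, 16 + 1:16], fm[, t1 - 1])
})

test_that("the full-size basis has the published feature count", {
  b <- splineBasis()
  expect_equal(prod(b@knots), 1080)          # 10 x 12 x 9
  expect_identical(b@dims, c(32L, 20L, 15L))
  expect_error(splineBasis(knots = c(3L, 4L, 4L)), "at least 4")
})

test_that("the penalized fit matches closed-form least squares at beta = 0", {
  set.seed(5)
  tiny <- fxTinyDesign()
  X <- tiny$des$X
  p <- ncol(X)
  btrue <- rnorm(p)
  y <- as.numeric(0.5 + X %*% btrue)          # noiseless target
  fit <- fitRF(X, y, beta = 0)
  mu <- colMeans(X)
  bls <- as.numeric(solve(crossprod(sweep(X, 2, mu)),
                          crossprod(sweep(X, 2, mu), y - mean(y))))
  relerr <- sqrt(sum((fit$coef - bls)^2) / sum(bls^2))
  expect_lt(relerr, 1e-4)
  expect_lt(max(abs(fit$coef - btrue)), 1e-2)
})

test_that("the L1 penalty shrinks coefficients and dominates in the limit", {
  set.seed(6)
  tiny <- fxTinyDesign()
  X <- tiny$des$X
  y <- rnorm(nrow(X))                          # pure-noise target
  f0 <- fitRF(X, y, beta = 0)
  f1 <- fitRF(X, y, beta = 0.01)
  expect_lt(sum(abs(f1$coef)), sum(abs(f0$coef)))
  fBig <- fitRF(X, y, beta = 10)   # 1000 x the default: penalty-dominated
  expect_lt(max(abs(fBig$coef)), 1e-8)
  expect_equal(fBig$intercept, mean(y), tolerance = 1e-8)
})

test_that("RF assembly and smoothing behave like the direct kernel", {
  b <- splineBasis(dims = c(8L, 6L, 5L), knots = c(4L, 4L, 4L))
  expect_equal(assembleRF(numeric(64), b), array(0, dim = c(8, 6, 5)))
  # assembleRF agrees with the materialized basis matrix
  set.seed(3)
  co <- rnorm(64)
  F1 <- assembleRF(co, b)
  F2 <- array(basisMatrix(b) %*% co, dim = c(8, 6, 5))
  expect_equal(F1, F2, tolerance = 1e-12)
  # smoothing an interior impulse reproduces the truncated Gaussian kernel
  Fimp <- array(0, dim = c(11, 11, 1))
  Fimp[6, 6, 1] <- 1
  sm <- smoothRF(Fimp)
  k <- rgcdegen:::.gaussKernel2d(5, 1)
  expect_equal(sm[4:8, 4:8, 1], k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-6)   # mass preserved
})

test_that("SVD split recovers separable structure and the quoted scalings", {
  g <- outer(exp(-((1:16) - 8)^2 / 8), exp(-((1:10) - 5)^2 / 6))
  h <- sin((1:7) / 2)
  F <- outer(g, h)
  sp <- svdSplit(F)
  expect_equal(sp$qi_svd, 1)
  expect_equal(max(abs(sp$Ft)), 1)
  expect_equal(max(abs(sp$Fs)), max(abs(F)))
  # orthogonal rank-1 contamination at 10% variance drops qi_svd to ~0.9
  set.seed(8)
  g2 <- matrix(rnorm(160), 16, 10); g2 <- g2 - g * sum(g2 * g) / sum(g * g)
  h2 <- cos((1:7)); h2 <- h2 - h * sum(h2 * h) / sum(h * h)
  C <- outer(g2, h2)
  C <- C * sqrt(0.1 * var(as.numeric(F)) / var(as.numeric(C)))
  sp2 <- svdSplit(F + C)
  expect_equal(sp2$qi_svd, 1 / 1.1, tolerance = 0.02)
  # scale invariance
  expect_equal(svdSplit(3.7 * F)$qi_svd, sp$qi_svd, tolerance = 1e-9)
  z <- svdSplit(array(0, dim = c(4, 4, 3)))
  expect_equal(z$qi_svd, 0)
})

test_that("spatial Gaussian self-fit recovers parameters and quality", {
  px <- 1:32; py <- 1:20
  Fs <- 2.5 * outer(exp(-(px - 14.3)^2 / (2 * 2.1^2)),
                    exp(-(py - 9.6)^2 / (2 * 3.4^2)))
  gf <- fitSpatialGaussian(Fs)
  expect_true(gf$ok)
  expect_gte(gf$qi_srf, 0.999)
  expect_equal(gf$params$x0, 14.3, tolerance = 0.01)
  expect_equal(gf$params$sigma_x, 2.1, tolerance = 0.02)
  expect_equal(gf$params$sigma_y, 3.4, tolerance = 0.03)
  # additive noise at ~20% variance gives qi_srf around 0.8
  set.seed(4)
  noise <- matrix(rnorm(640), 32, 20)
  noise <- noise * sqrt(0.25 * var(as.numeric(Fs)) / var(as.numeric(noise)))
  gf2 <- fitSpatialGaussian(Fs + noise)
  expect_equal(gf2$qi_srf, 0.8, tolerance = 0.1)
  # pure noise falls below the 0.5 gate
  gf3 <- fitSpatialGaussian(matrix(rnorm(640), 32, 20))
  expect_lt(gf3$qi_srf, 0.5)
  expect_error(fitSpatialGaussian(matrix(1, 5, 5)), "nonconstant")
})

test_that("RF size closed forms and scaling law", {
  s <- rfSize(25, 25)
  expect_equal(s$diameter_um, 100)
  expect_equal(s$area_um2, pi * 50 * 50)
  expect_equal(rfSize(9, 9)$diameter_um, 36)      # circular: d = 4 sigma
  s2 <- rfSize(50, 50)
  expect_equal(s2$area_um2 / s$area_um2, 4)
  expect_equal(s2$diameter_um / s$diameter_um, 2)
  expect_error(rfSize(0, 10), "positive")
})

test_that("main temporal peak takes the earliest qualifying peak", {
  lags <- seq(-0.2, 1.35, length.out = 15)
  Ft <- numeric(15)
  Ft[4] <- 1
  expect_equal(temporalPeaks(Ft, lags), lags[4])
  Ft2 <- numeric(15); Ft2[4] <- 0.8; Ft2[6] <- 1
  expect_equal(temporalPeaks(Ft2, lags), lags[4])  # smallest lag wins
  # nothing above 0.65 SD: undefined
  expect_true(is.na(temporalPeaks(rep(c(0.1, -0.1), length.out = 15), lags)))
})

test_that("RF quality gate applies strict boundaries", {
  expect_true(rfQualityGate(0.6, 0.6, 0.1))
  expect_false(rfQualityGate(0.5, 0.9, 0.1))    # boundary excluded
  expect_false(rfQualityGate(0.9, 0.5, 0.1))
  expect_false(rfQualityGate(0.9, 0.9, 0.35))   # outside the lag window
  expect_false(rfQualityGate(0.9, 0.9, NA))
  expect_true(rfQualityGate(0.9, 0.9, 0))
  expect_false(rfQualityGate(0.9, 0.9, 0.1, qiTrf = 0.5, useTrfGate = TRUE))
})

test_that("qi_srf expectation decreases with spatial noise variance", {
  set.seed(10)
  px <- 1:32; py <- 1:20
  Fs <- outer(exp(-(px - 16)^2 / 8), exp(-(py - 10)^2 / 8))
  q <- vapply(c(0.05, 0.2, 0.8), function(nv) {
    mean(replicate(10, {
      noise <- matrix(rnorm(640), 32, 20)
      noise <- noise * sqrt(nv * var(as.numeric(Fs)) / var(as.numeric(noise)))
      fitSpatialGaussian(Fs + noise)$qi_srf
    }))
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})
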