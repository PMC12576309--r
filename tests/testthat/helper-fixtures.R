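# Shared fixtures, built once per test run.

fx <- new.env()

fxLibrary <- function() {
  if (is.null(fx$lib)) fx$lib <- makeTypeLibrary(seed = 1)
  fx$lib
}

fxBasis <- function() {
  if (is.null(fx$basis)) fx$basis <- featureBasis(fxLibrary())
  fx$basis
}

fxChirp <- function() {
  if (is.null(fx$chirp)) fx$chirp <- makeChirp()
  fx$chirp
}

fxBar <- function() {
  if (is.null(fx$bar)) fx$bar <- makeMovingBar(seed = 1)
  fx$bar
}

# short noise stimulus for cheap tests
fxNoiseShort <- function() {
  if (is.null(fx$noiseShort))
    fx$noiseShort <- makeShiftedDenseNoise(duration = 30, seed = 3)
  fx$noiseShort
}

# tiny spline instance used by the optimizer oracle tests
fxTinyDesign <- function(T = 3000, seed = 5) {
  set.seed(seed)
  basis <- splineBasis(dims = c(6L, 4L, 5L), knots = c(4L, 4L, 4L))
  nf <- ceiling(T / 3)
  frames <- array(rbinom(6 * 4 * nf, 1, 0.5) - 0.5, dim = c(6, 4, nf))
  up <- list(frameIndex = rep(seq_len(nf), each = 3)[1:T],
             cdot = numeric(T), fsUp = 15)
  # lags spaced one stimulus frame apart (as in the full-size lag axis)
  lagSamples <- c(0L, 3L, 6L, 9L, 12L)
  des <- buildDesign(frames, basis, up, lagSamples)
  list(basis = basis, des = des, frames = frames, up = up,
       lagSamples = lagSamples)
}

# brute-force sliding Savitzky-Golay oracle: per-window polynomial LS fit
slidingPolySmooth <- function(x, win, order) {
  h <- (win - 1) %/% 2
  n <- length(x)
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])  # mirror padding
  tt <- -h:h
  P <- outer(tt, 0:order, "^")
  H <- P %*% solve(crossprod(P), t(P))
  w <- H[h + 1, ]
  vapply(seq_len(n), function(i) sum(w * xp[i:(i + win - 1)]), numeric(1))
}
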