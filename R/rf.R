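## Spatio-temporal receptive-field estimation from shifted dense-noise
## responses: spline-basis penalized linear-Gaussian model fit on the
## clipped temporal gradient of the detrended calcium signal.

#' Tensor cubic B-spline basis
#'
#' Constructs the per-axis cubic B-spline bases mapping
#' (kx, ky, ktau) = (10, 12, 9) coefficients to the (32, 20, 15) evaluation
#' grid. Coefficient/voxel order is x fastest, then y, then lag.
#'
#' @param dims evaluation grid c(dx, dy, dtau).
#' @param knots coefficients per axis c(kx, ky, ktau); each must be >= 4
#'   (cubic splines).
#' @return a [SplineBasis-class]
#' @export
splineBasis <- function(dims = c(32L, 20L, 15L), knots = c(10L, 12L, 9L)) {
  if (any(knots < 4)) stop("cubic B-splines need at least 4 coefficients per axis")
  ax <- function(d, k) {
    m <- unname(splines::bs(seq_len(d), df = k, intercept = TRUE,
                            degree = 3))
    matrix(as.numeric(m), nrow(m), ncol(m))
  }
  new("SplineBasis", dims = as.integer(dims), knots = as.integer(knots),
      Sx = ax(dims[1], knots[1]), Sy = ax(dims[2], knots[2]),
      St = ax(dims[3], knots[3]))
}

#' Materialized basis matrix
#'
#' The full (dx*dy*dtau) x (kx*ky*ktau) matrix S with F = S b. Intended for
#' small grids and oracle checks; the fitting path never materializes it.
#'
#' @param basis a [SplineBasis-class]
#' @return numeric matrix
#' @export
basisMatrix <- function(basis) {
  basis@St %x% basis@Sy %x% basis@Sx
}

#' Lag axis of the receptive-field model
#'
#' Fifteen lag taps spanning approximately -0.20 to +1.35 s, snapped to the
#' 50 Hz upsampled grid. Positive lags are causal (stimulus preceding the
#' response sample); the two acausal taps are kept for quality diagnostics.
#'
#' @param nLags number of taps.
#' @param lagRange lag range in s, c(min, max).
#' @param fsUp upsampled rate, Hz.
#' @return list with `samples` (integer lag in samples) and `seconds`
#' @export
rfLagAxis <- function(nLags = 15L, lagRange = c(-0.20, 1.35), fsUp = 50) {
  samp <- round(seq(lagRange[1], lagRange[2], length.out = nLags) * fsUp)
  list(samples = as.integer(samp), seconds = samp / fsUp)
}

#' Clipped temporal gradient of a calcium trace
#'
#' Forward-difference derivative scaled by the sample rate, with negative
#' values set to zero: an event-rate proxy for OGB-1 population imaging.
#' The final sample is padded with 0 to preserve length.
#'
#' @param trace detrended fluorescence series.
#' @param sampleRate sampling rate, Hz.
#' @return nonnegative series of the same length
#' @examples
#' clippedGradient(c(0, 1, 2, 1), sampleRate = 1)
#' @export
clippedGradient <- function(trace, sampleRate = RECORDING_RATE_HZ) {
  if (length(trace) < 2) stop("trace must have at least 2 samples")
  g <- c(diff(trace), 0) * sampleRate
  pmax(g, 0)
}

#' Upsample stimulus frames and rate signal onto a common 50 Hz grid
#'
#' The stimulus frame index is repeated (zero-order hold) at `factor` times
#' the frame rate, and the clipped gradient is linearly interpolated from
#' the recording grid onto the same grid, aligned at the stimulus onset
#' trigger. If the trace ends before the stimulus, the overlap is trimmed
#' and the number of dropped stimulus samples is reported.
#'
#' @param nFrames number of stimulus frames.
#' @param frameRate stimulus frame rate, Hz.
#' @param cdot clipped-gradient series on the recording grid.
#' @param sampleRate recording rate, Hz.
#' @param onsetS stimulus onset time within the trace, s.
#' @param factor upsampling factor relative to the frame rate.
#' @return list with `frameIndex` (stimulus frame per upsampled sample),
#'   `cdot` (interpolated rate), `fsUp`, and `dropped` (trimmed samples)
#' @export
upsamplePair <- function(nFrames, frameRate, cdot,
                         sampleRate = RECORDING_RATE_HZ,
                         onsetS, factor = 10L) {
  fsUp <- frameRate * factor
  nUp <- nFrames * factor
  tUp <- onsetS + (seq_len(nUp) - 1) / fsUp
  tTr <- (seq_along(cdot) - 1) / sampleRate
  keep <- tUp <= tTr[length(tTr)]
  dropped <- sum(!keep)
  if (dropped > 0)
    warning(sprintf("trace shorter than stimulus: %d upsampled samples trimmed", dropped))
  tUp <- tUp[keep]
  ci <- stats::approx(tTr, cdot, xout = tUp, rule = 2)$y
  list(frameIndex = rep(seq_len(nFrames), each = factor)[keep],
       cdot = ci, fsUp = fsUp, dropped = dropped)
}

#' Build spline-projected design features
#'
#' Computes the per-time-sample feature vectors X(t) S without materializing
#' the lagged design matrix: each frame is first projected through the
#' spatial bases (Sx' Frame Sy), the projections are upsampled by zero-order
#' hold, and the lagged copies are combined through the temporal basis. The
#' result has one row per valid time sample and kx*ky*ktau columns in the
#' coefficient order of [basisMatrix()]. Samples without full stimulus
#' history at the sequence edges are dropped.
#'
#' @param frames rasterized stimulus array (dx, dy, nFrames), contrast or
#'   intensity coded.
#' @param basis a [SplineBasis-class].
#' @param up result of [upsamplePair()] (provides the frame index per
#'   upsampled sample and the aligned rate signal).
#' @param lagSamples integer lags in upsampled samples
#'   (default [rfLagAxis()]).
#' @return list with `X` (features), `y` (aligned rate), `valid`
#'   (kept sample indices), `nDropped`
#' @export
buildDesign <- function(frames, basis, up,
                        lagSamples = rfLagAxis()$samples) {
  dx <- dim(frames)[1]; dy <- dim(frames)[2]; nf <- dim(frames)[3]
  stopifnot(dx == basis@dims[1], dy == basis@dims[2],
            length(lagSamples) == basis@dims[3])
  kx <- basis@knots[1]; ky <- basis@knots[2]; kt <- basis@knots[3]

  # spatial projection of every unique frame: nf x (kx*ky)
  fm <- matrix(frames, nrow = dx * dy)            # (dx*dy) x nf
  Sxy <- basis@Sy %x% basis@Sx                    # (dx*dy) x (kx*ky)
  P <- crossprod(fm, Sxy)                         # nf x (kx*ky)
  Pup <- P[up$frameIndex, , drop = FALSE]         # upsampled by ZOH

  nUp <- nrow(Pup)
  lo <- max(c(lagSamples, 0L)) + 1L
  hi <- nUp + min(c(lagSamples, 0L))
  if (hi <= lo) stop("sequence too short for the lag window")
  valid <- lo:hi
  nDropped <- nUp - length(valid)

  X <- matrix(0, length(valid), kx * ky * kt)
  for (j in seq_len(kt)) {
    acc <- matrix(0, length(valid), kx * ky)
    w <- basis@St[, j]
    for (l in seq_along(lagSamples)) {
      if (w[l] == 0) next
      acc <- acc + w[l] * Pup[valid - lagSamples[l], , drop = FALSE]
    }
    X[, ((j - 1) * kx * ky + 1):(j * kx * ky)] <- acc
  }
  list(X = X, y = up$cdot[valid], valid = valid, nDropped = nDropped)
}

#' Fit the penalized linear-Gaussian receptive-field model
#'
#' Minimizes L = (1/T) sum_t (c(t) - y0 - X(t) S b)^2 + beta |b|_1 by
#' full-batch Adam (learning rate 0.1, beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8), trained for at least `minSteps` and at most `maxSteps`
#' steps; if the loss finds no new best for `patience` consecutive steps the
#' fit stops and the lowest-loss parameters are returned. Gradients are
#' computed from precomputed Gram matrices (algebraically identical to the
#' full-batch gradient); features are standardized internally and the
#' coefficients mapped back, which conditions the problem without changing
#' the beta = 0 optimum.
#'
#' @param X feature matrix (time x coefficients), e.g. from [buildDesign()].
#' @param y target rate series.
#' @param beta L1 penalty weight.
#' @param lr Adam learning rate.
#' @param minSteps,maxSteps,patience training schedule.
#' @param seed integer seed (kept for interface symmetry; the fit is
#'   deterministic).
#' @return list with `coef`, `intercept`, `loss` (per-step trace),
#'   `steps`, `converged`
#' @export
fitRF <- function(X, y, beta = 0.01, lr = 0.1, minSteps = 100L,
                  maxSteps = 2000L, patience = 5L, seed = 1L) {
  stopifnot(nrow(X) == length(y), beta >= 0)
  T <- length(y)
  mu <- colMeans(X)
  sdv <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  sdv[sdv < 1e-12] <- 1
  Xc <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ybar <- mean(y)

  XtX <- crossprod(Xc)
  Xty <- as.numeric(crossprod(Xc, y - ybar))
  yy <- sum((y - ybar)^2)
  p <- ncol(X)
  # penalty applies to the raw-scale coefficients b_raw = b_std / sdv
  penW <- beta / sdv

  b <- numeric(p); a <- 0    # a = intercept offset from ybar
  m <- numeric(p + 1); v <- numeric(p + 1)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- yy / T             # loss at the zero initialization
  bestPar <- c(b, a); bad <- 0L; lossTrace <- numeric(0)
  converged <- FALSE; improved <- FALSE
  for (s in seq_len(maxSteps)) {
    # Adam on the smooth (quadratic) part, proximal soft-threshold for the
    # L1 part: a plain subgradient step leaves every near-zero coefficient
    # oscillating at the learning-rate scale and the penalty never settles
    gb <- as.numeric(2 / T * (XtX %*% b - Xty))
    ga <- 2 * a
    g <- c(gb, ga)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    scale <- lr / (sqrt(v / (1 - b2^s)) + eps)
    par <- c(b, a) - scale * (m / (1 - b1^s))
    thr <- scale[seq_len(p)] * penW
    par[seq_len(p)] <- sign(par[seq_len(p)]) *
      pmax(abs(par[seq_len(p)]) - thr, 0)
    b <- par[seq_len(p)]; a <- par[p + 1]
    loss <- (yy - 2 * sum(b * Xty) +
               as.numeric(crossprod(b, XtX %*% b))) / T + a^2 +
      sum(penW * abs(b))
    if (!is.finite(loss))
      stop("non-finite loss during RF fitting; try a smaller learning rate")
    lossTrace <- c(lossTrace, loss)
    if (loss < best) {  # "improved" = any new best loss
      best <- loss; bestPar <- par; bad <- 0L; improved <- TRUE
    } else bad <- bad + 1L
    # early stopping engages only once training has beaten the zero
    # initialization: Adam's first-steps transient must not count as a
    # plateau (if nothing ever improves, the zero solution is returned
    # after maxSteps - the penalty-dominated regime)
    if (s >= minSteps && bad >= patience && improved) {
      converged <- TRUE; break
    }
  }
  list(coef = bestPar[seq_len(p)] / sdv,
       intercept = ybar + bestPar[p + 1] - sum(bestPar[seq_len(p)] / sdv * mu),
       loss = lossTrace, steps = length(lossTrace), converged = converged)
}

#' Select the L1 penalty by held-out prediction
#'
#' Fits the RF model over a grid of penalty weights on the first part of the
#' recording and scores each by mean squared prediction error on the
#' held-out tail - the same hyperparameter-optimization logic used to set
#' the published defaults, applicable when the data scale differs.
#'
#' @param X,y design features and target, as for [fitRF()].
#' @param grid candidate penalty weights.
#' @param holdout fraction of samples held out (taken from the end).
#' @param ... passed to [fitRF()].
#' @return list with `beta` (the winner), `mse` (named validation errors)
#' @export
selectRFPenalty <- function(X, y, grid = c(0.003, 0.01, 0.03, 0.1, 0.3),
                            holdout = 0.2, ...) {
  n <- nrow(X)
  cut <- floor((1 - holdout) * n)
  mse <- vapply(grid, function(b) {
    fit <- fitRF(X[1:cut, , drop = FALSE], y[1:cut], beta = b, ...)
    pred <- as.numeric(X[(cut + 1):n, , drop = FALSE] %*% fit$coef) +
      fit$intercept
    mean((y[(cut + 1):n] - pred)^2)
  }, numeric(1))
  names(mse) <- grid
  list(beta = grid[which.min(mse)], mse = mse)
}

#' Assemble the receptive field from spline coefficients
#'
#' F(x, y, tau) = S b on the evaluation grid, computed axis-by-axis.
#'
#' @param b coefficient vector (kx*ky*ktau).
#' @param basis a [SplineBasis-class].
#' @return numeric array (dx, dy, dtau)
#' @export
assembleRF <- function(b, basis) {
  kx <- basis@knots[1]; ky <- basis@knots[2]; kt <- basis@knots[3]
  stopifnot(length(b) == kx * ky * kt)
  B <- array(b, dim = c(kx, ky, kt))
  # contract each axis in turn
  M1 <- basis@Sx %*% matrix(B, kx, ky * kt)                 # dx x (ky kt)
  A1 <- array(M1, c(basis@dims[1], ky, kt))
  M2 <- basis@Sy %*% matrix(aperm(A1, c(2, 1, 3)), ky)      # dy x (dx kt)
  A2 <- aperm(array(M2, c(basis@dims[2], basis@dims[1], kt)), c(2, 1, 3))
  M3 <- basis@St %*% matrix(aperm(A2, c(3, 1, 2)), kt)      # dt x (dx dy)
  aperm(array(M3, c(basis@dims[3], basis@dims[1], basis@dims[2])),
        c(2, 3, 1))
}

.gaussKernel2d <- function(size = 5L, sd = 1) {
  h <- size %/% 2L
  g <- exp(-((-h):h)^2 / (2 * sd^2))
  k <- outer(g, g)
  k / sum(k)
}

.smoothFrame <- function(M, k) {
  p <- nrow(k) %/% 2L
  nr <- nrow(M); nc <- ncol(M)
  # reflective (mirror) padding
  ri <- c((p + 1L):2L, 1:nr, (nr - 1L):(nr - p))
  ci <- c((p + 1L):2L, 1:nc, (nc - 1L):(nc - p))
  Mp <- M[ri, ci]
  out <- matrix(0, nr, nc)
  for (a in seq_len(2L * p + 1L)) for (b in seq_len(2L * p + 1L))
    out <- out + k[a, b] * Mp[(a):(a + nr - 1L), (b):(b + nc - 1L)]
  out
}

#' Smooth a receptive field frame-by-frame
#'
#' Applies a 5 x 5 pixel Gaussian filter (sd = 1 px) to each lag frame,
#' with reflective borders.
#'
#' @param F array (dx, dy, dtau).
#' @param size,sd filter size (px, odd) and standard deviation (px).
#' @return smoothed array of the same shape
#' @export
smoothRF <- function(F, size = 5L, sd = 1) {
  k <- .gaussKernel2d(size, sd)
  out <- F
  for (l in seq_len(dim(F)[3])) out[, , l] <- .smoothFrame(F[, , l], k)
  out
}

#' Rank-1 SVD split of a spatio-temporal RF
#'
#' Decomposes F into a temporal component Ft(tau) and spatial component
#' Fs(x, y) via SVD of the (space x lag) matricization, scaled so
#' max|Ft| = 1 and max|Fs| = max|F|. The sign pair is chosen so the
#' temporal component's largest-magnitude sample is positive (response
#' polarity is carried by the spatial component). The SVD quality index is
#' QI_SVD = 1 - Var\[F - rank1(F)\] / Var\[F\].
#'
#' @param F array (dx, dy, dtau).
#' @return list with `Ft`, `Fs`, `qi_svd`
#' @export
svdSplit <- function(F) {
  d <- dim(F)
  if (max(abs(F)) == 0)
    return(list(Ft = numeric(d[3]), Fs = matrix(0, d[1], d[2]), qi_svd = 0))
  M <- matrix(F, nrow = d[1] * d[2])    # space x lag
  sv <- svd(M, nu = 1, nv = 1)
  u <- sv$u[, 1]; w <- sv$v[, 1]
  if (w[which.max(abs(w))] < 0) { w <- -w; u <- -u }
  rank1 <- sv$d[1] * tcrossprod(u, w)
  qi <- 1 - .varPop(as.numeric(M - rank1)) / .varPop(as.numeric(M))
  Ft <- w / max(abs(w))
  Fs <- matrix(u / max(abs(u)) * max(abs(F)), d[1], d[2])
  list(Ft = Ft, Fs = Fs, qi_svd = min(max(qi, 0), 1))
}

#' Fit a 2D elliptical Gaussian to a spatial RF
#'
#' Nonlinear least-squares fit of amplitude, center, sigma_x, sigma_y and
#' rotation angle (no offset term), initialized from the peak pixel and
#' image moments. The fit quality is
#' QI_sRF = 1 - Var(Fs - F_Gauss) / Var(Fs). Non-convergence yields
#' qi_srf = 0 and a flagged fit.
#'
#' @param Fs spatial RF matrix (dx x dy).
#' @param pixelUm pixel size in um (for reporting sigma in um).
#' @return list with `params` (amplitude, x0, y0, sigma_x, sigma_y, theta,
#'   in px; sigma_x_um, sigma_y_um), `qi_srf`, `ok`
#' @export
fitSpatialGaussian <- function(Fs, pixelUm = RF_PIXEL_UM) {
  if (.varPop(as.numeric(Fs)) == 0) stop("Fs must be nonconstant")
  nx <- nrow(Fs); ny <- ncol(Fs)
  df <- data.frame(z = as.numeric(Fs),
                   x = rep(seq_len(nx), times = ny),
                   y = rep(seq_len(ny), each = nx))
  i0 <- which.max(abs(df$z))
  A0 <- df$z[i0]
  w <- abs(df$z) / sum(abs(df$z))
  sx0 <- max(sqrt(sum(w * (df$x - df$x[i0])^2)) / 2, 1)
  sy0 <- max(sqrt(sum(w * (df$y - df$y[i0])^2)) / 2, 1)
  fit <- try(minpack.lm::nlsLM(
    z ~ A * exp(-((cos(th) * (x - x0) + sin(th) * (y - y0))^2 / (2 * sx^2) +
                  (-sin(th) * (x - x0) + cos(th) * (y - y0))^2 / (2 * sy^2))),
    data = df,
    start = list(A = A0, x0 = df$x[i0], y0 = df$y[i0],
                 sx = sx0, sy = sy0, th = 0),
    lower = c(-Inf, 0, 0, 0.3, 0.3, -pi),
    upper = c(Inf, nx + 1, ny + 1, nx, ny, pi),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(params = NULL, qi_srf = 0, ok = FALSE))
  cf <- as.list(coef(fit))
  pred <- predict(fit)
  qi <- 1 - .varPop(df$z - pred) / .varPop(df$z)
  params <- list(amplitude = cf$A, x0 = cf$x0, y0 = cf$y0,
                 sigma_x = abs(cf$sx), sigma_y = abs(cf$sy), theta = cf$th,
                 sigma_x_um = abs(cf$sx) * pixelUm,
                 sigma_y_um = abs(cf$sy) * pixelUm)
  list(params = params, qi_srf = min(max(qi, 0), 1), ok = TRUE)
}

#' Receptive-field size from the Gaussian fit
#'
#' The area covered by two standard deviations of the fitted Gaussian:
#' A = pi (2 sigma_x)(2 sigma_y), reported together with the equivalent
#' diameter d = 2 sqrt(A / pi) = 4 sqrt(sigma_x sigma_y).
#'
#' @param sigmaXUm,sigmaYUm Gaussian standard deviations in um (> 0).
#' @return list with `area_um2` and `diameter_um`
#' @examples
#' rfSize(25, 25)  # d = 100 um
#' @export
rfSize <- function(sigmaXUm, sigmaYUm) {
  if (sigmaXUm <= 0 || sigmaYUm <= 0)
    stop("sigma must be positive")
  list(area_um2 = pi * (2 * sigmaXUm) * (2 * sigmaYUm),
       diameter_um = 4 * sqrt(sigmaXUm * sigmaYUm))
}

#' Main temporal peak lag
#'
#' Detects local maxima of |Ft| exceeding 0.65 population standard
#' deviations of Ft (endpoints excluded) and returns the lag of the
#' qualifying peak with the smallest lag value, in seconds. Returns NA if
#' no peak qualifies, which fails the RF quality gate.
#'
#' @param Ft temporal RF (max |Ft| = 1).
#' @param lags lag axis in s, same length as Ft, increasing.
#' @param minHeightSd peak threshold in SDs of Ft.
#' @return main peak lag in s, or NA
#' @export
temporalPeaks <- function(Ft, lags = rfLagAxis()$seconds,
                          minHeightSd = 0.65) {
  stopifnot(length(Ft) == length(lags))
  a <- abs(Ft)
  thr <- minHeightSd * sqrt(.varPop(Ft))
  n <- length(a)
  isPeak <- rep(FALSE, n)
  for (i in 2:(n - 1))
    isPeak[i] <- a[i] > a[i - 1] && a[i] >= a[i + 1] && a[i] > thr
  if (!any(isPeak)) return(NA_real_)
  min(lags[isPeak])
}

#' RF quality gate
#'
#' An RF is used for analysis only if QI_SVD > 0.5, QI_sRF > 0.5 (strict)
#' and its main peak lag lies between 0 and 0.3 s. An undefined lag fails.
#' An optional temporal-fit-quality gate (QI_tRF > 0.85) can be enabled.
#'
#' @param qiSvd,qiSrf quality indices.
#' @param mainPeakLag main peak lag in s (NA allowed).
#' @param qiTrf optional temporal quality index.
#' @param useTrfGate whether to apply the QI_tRF > 0.85 gate.
#' @return logical
#' @examples
#' rfQualityGate(0.6, 0.6, 0.1)   # TRUE
#' rfQualityGate(0.5, 0.9, 0.1)   # FALSE (boundary excluded)
#' @export
rfQualityGate <- function(qiSvd, qiSrf, mainPeakLag, qiTrf = NA,
                          useTrfGate = FALSE) {
  ok <- isTRUE(qiSvd > 0.5) && isTRUE(qiSrf > 0.5) &&
    !is.na(mainPeakLag) && mainPeakLag >= 0 && mainPeakLag <= 0.3
  if (useTrfGate) ok <- ok && isTRUE(qiTrf > 0.85)
  ok
}

#' Estimate a cell's receptive field end-to-end
#'
#' Full RF pipeline for one cell: detrend the noise-stimulus trace, take the
#' clipped temporal gradient, upsample to 10x the stimulus frame rate, build
#' the spline-projected design from the rasterized (contrast-coded) frames,
#' fit the penalized linear-Gaussian model, assemble and smooth the RF,
#' split it by SVD, fit the spatial Gaussian, measure size (corrected for
#' the known smoothing blur by subtracting its variance from the fitted
#' sigma^2) and kinetics, and apply the quality gates.
#'
#' @param trace raw fluorescence trace for the noise stimulus.
#' @param noise the [ShiftedDenseNoise-class] presented.
#' @param onsetS stimulus onset time within the trace, s.
#' @param basis a [SplineBasis-class].
#' @param sampleRate recording rate, Hz.
#' @param beta,lr,minSteps,maxSteps,patience passed to [fitRF()].
#' @param frames optional precomputed rasterized frames (contrast-coded);
#'   pass when fitting many cells of one field to avoid re-rasterizing.
#' @param design optional precomputed spatial design info (advanced).
#' @param smoothSd smoothing SD in px (also the size-correction term).
#' @return an [RFModel-class]
#' @export
estimateRF <- function(trace, noise, onsetS, basis = splineBasis(),
                       sampleRate = RECORDING_RATE_HZ,
                       beta = 0.01, lr = 0.1, minSteps = 100L,
                       maxSteps = 2000L, patience = 5L,
                       frames = NULL, smoothSd = 1) {
  if (is.null(frames)) frames <- rasterizeNoise(noise) - 0.5
  det <- detrendTrace(trace, sampleRate)
  cdot <- clippedGradient(det, sampleRate)
  up <- upsamplePair(dim(frames)[3], noise@frameRate, cdot,
                     sampleRate, onsetS)
  lag <- rfLagAxis(nLags = basis@dims[3])
  des <- buildDesign(frames, basis, up, lag$samples)
  fit <- fitRF(des$X, des$y, beta = beta, lr = lr, minSteps = minSteps,
               maxSteps = maxSteps, patience = patience)
  Fraw <- assembleRF(fit$coef, basis)
  Fsm <- smoothRF(Fraw, sd = smoothSd)
  sp <- svdSplit(Fsm)
  mainLag <- if (max(abs(sp$Ft)) > 0)
    temporalPeaks(sp$Ft, lag$seconds) else NA_real_

  gfit <- if (.varPop(as.numeric(sp$Fs)) > 0)
    fitSpatialGaussian(sp$Fs) else list(params = NULL, qi_srf = 0, ok = FALSE)
  size <- list(area_um2 = NA_real_, diameter_um = NA_real_,
               diameter_raw_um = NA_real_)
  if (gfit$ok) {
    # remove the deliberate smoothing blur from the size estimate
    sxc <- sqrt(max(gfit$params$sigma_x^2 - smoothSd^2, 0.05))
    syc <- sqrt(max(gfit$params$sigma_y^2 - smoothSd^2, 0.05))
    sz <- rfSize(sxc * RF_PIXEL_UM, syc * RF_PIXEL_UM)
    szRaw <- rfSize(gfit$params$sigma_x_um, gfit$params$sigma_y_um)
    size <- list(area_um2 = sz$area_um2, diameter_um = sz$diameter_um,
                 diameter_raw_um = szRaw$diameter_um)
  }
  # optional temporal quality diagnostic: fraction of temporal-RF energy at
  # causal (non-negative) lags
  qiTrf <- if (sum(sp$Ft^2) > 0)
    sum(sp$Ft[lag$seconds >= 0]^2) / sum(sp$Ft^2) else 0

  new("RFModel",
      coef = fit$coef, intercept = fit$intercept, basis = basis,
      F = Fsm, Ft = sp$Ft, Fs = sp$Fs, lags = lag$seconds,
      gauss = if (gfit$ok) gfit$params else list(),
      rfSize = size,
      mainPeakLag = if (is.na(mainLag)) NA_real_ else mainLag,
      qiSvd = sp$qi_svd, qiSrf = gfit$qi_srf, qiTrf = qiTrf,
      passesQuality = rfQualityGate(sp$qi_svd, gfit$qi_srf, mainLag),
      fit = list(loss = fit$loss, steps = fit$steps,
                 converged = fit$converged, nDropped = des$nDropped))
}
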