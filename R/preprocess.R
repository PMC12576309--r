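## Trace preprocessing: Savitzky-Golay detrending, baseline normalization,
## trial snippeting, and the repeatability quality index used for
## responsiveness gating.

## cache of central Savitzky-Golay coefficients, keyed by (order, window)
.sgCache <- new.env(parent = emptyenv())

.sgCoefs <- function(order, win) {
  key <- sprintf("p%d_n%d", order, win)
  if (is.null(.sgCache[[key]]))
    .sgCache[[key]] <- signal::sgolay(p = order, n = win)[(win - 1L) %/% 2L + 1L, ]
  .sgCache[[key]]
}

#' Detrend a fluorescence trace
#'
#' Subtracts a Savitzky-Golay-smoothed version of the trace (third
#' polynomial order, 60 s window by default) to remove slow drifts in the
#' calcium signal: r_detrend = r_raw - r_smooth. The window is converted to
#' the nearest odd sample count; edges are handled by mirror padding so the
#' central filter coefficients apply throughout.
#'
#' @param trace numeric fluorescence series.
#' @param sampleRate sampling rate, Hz.
#' @param windowS smoothing window length, s.
#' @param order polynomial order of the filter.
#' @return detrended series of the same length
#' @examples
#' x <- sin(seq(0, 20, by = 1/7.8125)) + seq(0, 5, length.out = 157)
#' d <- detrendTrace(x, 7.8125, windowS = 10)
#' @export
detrendTrace <- function(trace, sampleRate = RECORDING_RATE_HZ,
                         windowS = 60, order = 3) {
  win <- round(windowS * sampleRate)
  if (win %% 2 == 0) win <- win + 1L
  if (length(trace) <= win)
    stop(sprintf(
      "trace too short for detrending: %d samples, need more than %d (%g s at %g Hz)",
      length(trace), win, windowS, sampleRate))
  h <- (win - 1L) %/% 2L
  coefs <- .sgCoefs(order, win)
  padded <- c(trace[(h + 1L):2L], trace, trace[(length(trace) - 1L):(length(trace) - h)])
  sm <- stats::filter(padded, coefs, method = "convolution", sides = 2)
  sm <- as.numeric(sm)[(h + 1L):(h + length(trace))]
  trace - sm
}

#' Baseline-subtract and peak-normalize a trace
#'
#' Subtracts the baseline activity (mean of the first 8 samples) and scales
#' the trace so that its maximum equals 1. Cells whose post-baseline maximum
#' is non-positive (or numerically negligible) cannot be normalized this way
#' and are flagged out rather than sign-flipped.
#'
#' @param trace numeric series (detrended), length >= 8.
#' @param floor numerical floor below which the maximum counts as
#'   non-positive.
#' @return list with `trace` (normalized series, or NULL), `ok` (logical),
#'   `baseline` (subtracted mean) and `scale` (the division factor).
#' @examples
#' baselineNormalize(c(rep(5, 8), 10, 15))
#' @export
baselineNormalize <- function(trace, floor = 1e-9) {
  if (length(trace) < 8)
    stop("trace must have at least 8 samples")
  m <- mean(trace[1:8])
  x <- trace - m
  M <- max(x)
  if (!is.finite(M) || M <= floor)
    return(list(trace = NULL, ok = FALSE, baseline = m, scale = NA_real_))
  list(trace = x / M, ok = TRUE, baseline = m, scale = M)
}

#' Cut a trace into a trial response matrix
#'
#' Extracts one column of `snippetLen` samples per trigger, starting at the
#' sample nearest to each trigger time, forming the T x R response matrix C
#' (time samples x stimulus repetitions).
#'
#' @param trace numeric series.
#' @param triggersS trigger times in s (>= 2 required).
#' @param snippetLen snippet length in samples.
#' @param sampleRate sampling rate, Hz.
#' @return numeric matrix (snippetLen x length(triggersS))
#' @examples
#' snippetize(0:99, c(0, 10), snippetLen = 5, sampleRate = 1)
#' @export
snippetize <- function(trace, triggersS, snippetLen,
                       sampleRate = RECORDING_RATE_HZ) {
  if (length(triggersS) < 2)
    stop("at least 2 triggers are required")
  starts <- round(triggersS * sampleRate) + 1L
  bad <- which(starts + snippetLen - 1L > length(trace))
  if (length(bad))
    stop("trigger(s) beyond trace end: ",
         paste(sprintf("%.2f s", triggersS[bad]), collapse = ", "))
  vapply(starts, function(s) trace[s:(s + snippetLen - 1L)],
         numeric(snippetLen))
}

.varPop <- function(x) mean((x - mean(x))^2)

#' Response quality index
#'
#' Repeatability of a trial response matrix C (T x R):
#' QI = Var\[<C>_r\]_t / <Var\[C\]_t>_r - the temporal variance of the
#' trial-mean response over the trial-average of per-trial temporal
#' variances, with population variances throughout. QI is 1 for perfectly
#' repeatable responses and tends to 1/R for independent noise. The value is
#' clipped to \[0, 1\]; an all-constant matrix (zero denominator) yields 0.
#'
#' @param C numeric matrix, time samples x repetitions (T >= 2, R >= 2).
#' @return QI in \[0, 1\]
#' @examples
#' qualityIndex(cbind(sin(1:50), sin(1:50)))  # 1
#' @export
qualityIndex <- function(C) {
  if (!is.matrix(C) || nrow(C) < 2 || ncol(C) < 2)
    stop("C must be a T x R matrix with T >= 2 and R >= 2")
  den <- mean(apply(C, 2, .varPop))
  if (den == 0) return(0)
  num <- .varPop(rowMeans(C))
  min(max(num / den, 0), 1)
}

#' Responsiveness gate
#'
#' A cell counts as responsive if its chirp quality index reaches 0.35 or
#' its moving-bar quality index reaches 0.6 (inclusive thresholds). Missing
#' indices (NA) fail their branch.
#'
#' @param qiChirp,qiMb quality indices in \[0, 1\] (NA allowed).
#' @param thChirp,thMb the gate thresholds.
#' @return logical
#' @examples
#' gateResponsive(0.35, 0)   # TRUE
#' gateResponsive(0.34, 0.59)  # FALSE
#' @export
gateResponsive <- function(qiChirp, qiMb, thChirp = 0.35, thMb = 0.6) {
  a <- !is.na(qiChirp) & qiChirp >= thChirp
  b <- !is.na(qiMb) & qiMb >= thMb
  a | b
}

#' Preprocess a cohort
#'
#' Runs detrending, baseline normalization, snippeting and quality indexing
#' for every cell and every presented repeated stimulus. Chirp snippets use
#' one column per repetition; moving-bar snippets use one column per trial
#' (direction x repetition). Cells that cannot be baseline-normalized for a
#' stimulus get NA quality for it.
#'
#' @param cohort an [RGCCohort-class]
#' @return list with:
#'   \describe{
#'     \item{qi}{data.frame with cell_id, qi_chirp, qi_mb, responsive}
#'     \item{snippets}{named list of 3D arrays (time x trial x cell) of
#'       normalized snippets; NA planes where normalization failed}
#'     \item{detrended}{named list of detrended trace matrices}
#'   }
#' @export
preprocessCohort <- function(cohort) {
  fs <- cohort@sampleRate
  n <- nCells(cohort)
  out <- list(qi = data.frame(cell_id = cellData(cohort)$cell_id,
                              qi_chirp = NA_real_, qi_mb = NA_real_,
                              responsive = FALSE,
                              stringsAsFactors = FALSE),
              snippets = list(), detrended = list())

  specs <- list()
  if ("chirp" %in% names(cohort@traces)) {
    per <- chirpPeriod(cohort@stimuli$chirp)
    specs$chirp <- list(len = floor(per * fs), qiCol = "qi_chirp")
  }
  if ("bar" %in% names(cohort@traces)) {
    mb <- cohort@stimuli$bar
    per <- mb@sweepDuration + mb@gapDuration
    specs$bar <- list(len = floor(per * fs), qiCol = "qi_mb")
  }

  for (nm in names(specs)) {
    tr <- cohort@traces[[nm]]
    trig <- cohort@triggers[[nm]]
    len <- specs[[nm]]$len
    det <- apply(tr, 2, detrendTrace, sampleRate = fs)
    snip <- array(NA_real_, dim = c(len, length(trig), n))
    qi <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      bn <- baselineNormalize(det[, i])
      if (!bn$ok) next
      C <- snippetize(bn$trace, trig, len, fs)
      snip[, , i] <- C
      qi[i] <- qualityIndex(C)
    }
    out$qi[[specs[[nm]]$qiCol]] <- qi
    out$snippets[[nm]] <- snip
    out$detrended[[nm]] <- det
  }
  out$qi$responsive <- gateResponsive(out$qi$qi_chirp, out$qi$qi_mb)
  out
}
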