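## Direction and orientation selectivity from moving-bar responses.

#' SVD tuning curve across motion directions
#'
#' Stacks the per-direction mean snippets into a time x direction matrix and
#' takes its best rank-1 factorization: the time component captures the
#' common response waveform, and the direction component (times the singular
#' value) is the tuning curve. Signs are aligned so the time component's
#' largest-magnitude sample is positive, and the tuning curve is rectified
#' at zero.
#'
#' @param CbyDir either a list of T x R matrices (one per direction) or a
#'   3D array (T x R x nDir).
#' @return list with `tuning` (nonnegative amplitude per direction),
#'   `time` (unit time component) and `meanByDir` (T x nDir matrix)
#' @export
tuningCurve <- function(CbyDir) {
  if (is.array(CbyDir) && length(dim(CbyDir)) == 3)
    CbyDir <- lapply(seq_len(dim(CbyDir)[3]), function(k) CbyDir[, , k])
  if (any(vapply(CbyDir, ncol, integer(1)) < 2))
    stop("at least 2 trials per direction are required")
  M <- vapply(CbyDir, rowMeans, numeric(nrow(CbyDir[[1]])))
  nd <- ncol(M)
  if (max(abs(M)) == 0)
    return(list(tuning = numeric(nd), time = numeric(nrow(M)),
                meanByDir = M))
  sv <- svd(M, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1] * sv$d[1]
  if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
  list(tuning = pmax(v, 0), time = u, meanByDir = M)
}

.complexProjection <- function(tuning, directions, harmonic = 1) {
  s <- sum(tuning)
  if (s <= 0) return(0)
  th <- directions * pi / 180
  Mod(sum(tuning * exp(1i * harmonic * th))) / s
}

#' Direction selectivity index
#'
#' Modulus of the amplitude-weighted mean unit vector over directions:
#' DSI = |sum_k r_k e^(i theta_k)| / sum_k r_k. 0 for direction-flat tuning,
#' 1 when all amplitude sits in a single direction.
#'
#' @param tuning nonnegative amplitude per direction.
#' @param directions direction angles in degrees.
#' @return DSI in \[0, 1\]
#' @examples
#' dsi(c(2, 1, 1, 1, 1, 1, 1, 1), seq(0, 315, by = 45))  # 1/9
#' @export
dsi <- function(tuning, directions) {
  stopifnot(length(tuning) == length(directions))
  .complexProjection(tuning, directions, harmonic = 1)
}

#' Orientation selectivity index
#'
#' As [dsi()] but with doubled angles, so amplitudes at theta and
#' theta + 180 degrees reinforce instead of cancel.
#'
#' @inheritParams dsi
#' @return OSI in \[0, 1\]
#' @export
osi <- function(tuning, directions) {
  stopifnot(length(tuning) == length(directions))
  .complexProjection(tuning, directions, harmonic = 2)
}

#' Per-trial response amplitudes for the permutation test
#'
#' Projects each trial snippet onto the SVD time component of the tuning
#' construction, giving one scalar amplitude per trial, consistent with how
#' the tuning curve itself is built.
#'
#' @param CbyDir list of T x R matrices (one per direction) or 3D array.
#' @param time unit time component from [tuningCurve()]; recomputed if NULL.
#' @return list with `amplitude` (one per trial) and `direction_index`
#'   (integer label per trial)
#' @export
trialAmplitudes <- function(CbyDir, time = NULL) {
  if (is.array(CbyDir) && length(dim(CbyDir)) == 3)
    CbyDir <- lapply(seq_len(dim(CbyDir)[3]), function(k) CbyDir[, , k])
  if (is.null(time)) time <- tuningCurve(CbyDir)$time
  amps <- lapply(CbyDir, function(C) as.numeric(crossprod(C, time)))
  list(amplitude = unlist(amps),
       direction_index = rep(seq_along(CbyDir),
                             vapply(CbyDir, ncol, integer(1))))
}

.statFromLabels <- function(amplitude, labels, directions, harmonic) {
  r <- vapply(seq_along(directions),
              function(k) mean(amplitude[labels == k]), numeric(1))
  .complexProjection(pmax(r, 0), directions, harmonic)
}

#' Permutation test for direction (or orientation) selectivity
#'
#' Shuffles direction labels across trials and recomputes the selectivity
#' index; the p-value uses the add-one estimator
#' p = (1 + #\{permuted >= observed\}) / (1 + nPerm), which is valid (never
#' anti-conservative) for any nPerm.
#'
#' @param amplitude per-trial response amplitude.
#' @param directionIndex integer direction label per trial (1..nDir).
#' @param directions direction angles in degrees.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @param harmonic 1 for direction, 2 for orientation selectivity.
#' @return list with `p`, `observed` and `null` (permuted statistics)
#' @export
permutationTestDS <- function(amplitude, directionIndex,
                              directions = seq(0, 315, by = 45),
                              nPerm = 1000L, seed = 1L, harmonic = 1) {
  if (length(unique(directionIndex)) < 2)
    return(list(p = 1, observed = NA_real_, null = numeric(0)))
  if (nPerm < 100) stop("nPerm must be >= 100")
  if (min(table(directionIndex)) < 2)
    stop("at least 2 trials per direction are required")
  obs <- .statFromLabels(amplitude, directionIndex, directions, harmonic)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- length(amplitude)
  # shuffling labels across trials is equivalent to permuting amplitudes
  A <- vapply(seq_len(nPerm), function(b) amplitude[sample.int(n)],
              numeric(n))
  cnt <- as.numeric(table(factor(directionIndex,
                                 levels = seq_along(directions))))
  r <- pmax(rowsum(A, directionIndex) / cnt, 0)   # nDir x nPerm means
  e <- exp(1i * harmonic * directions * pi / 180)
  tot <- colSums(r)
  null <- ifelse(tot > 0, Mod(colSums(r * e)) / tot, 0)
  list(p = (1 + sum(null >= obs)) / (1 + nPerm), observed = obs, null = null)
}

#' Tuning analysis for one cell
#'
#' Convenience wrapper: builds the SVD tuning curve from per-trial bar
#' snippets, computes DSI/OSI and both permutation p-values.
#'
#' @param barSnippets T x nTrial matrix of normalized bar snippets (trial
#'   order as presented).
#' @param trialDirections direction in degrees for each trial.
#' @param directions the direction set.
#' @param nPerm permutations for each test.
#' @param seed integer seed.
#' @return list with `tuning`, `dsi`, `osi`, `p_ds`, `p_os`
#' @export
tuningAnalysis <- function(barSnippets, trialDirections,
                           directions = seq(0, 315, by = 45),
                           nPerm = 1000L, seed = 1L) {
  idx <- match(trialDirections, directions)
  if (any(is.na(idx))) stop("trial direction not in direction set")
  CbyDir <- lapply(seq_along(directions),
                   function(k) barSnippets[, idx == k, drop = FALSE])
  tc <- tuningCurve(CbyDir)
  ta <- trialAmplitudes(CbyDir, tc$time)
  # trialAmplitudes orders trials by direction group; labels accordingly
  pd <- permutationTestDS(ta$amplitude, ta$direction_index, directions,
                          nPerm = nPerm, seed = seed, harmonic = 1)
  po <- permutationTestDS(ta$amplitude, ta$direction_index, directions,
                          nPerm = nPerm, seed = seed + 1L, harmonic = 2)
  list(tuning = tc$tuning, time = tc$time,
       dsi = dsi(tc$tuning, directions), osi = osi(tc$tuning, directions),
       p_ds = pd$p, p_os = po$p)
}
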