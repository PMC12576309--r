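## Stimulus generators: chirp, moving bar, shifted dense noise.
## All generators are pure functions of (config, seed).

#' Generate the full-field chirp stimulus
#'
#' Builds the chirp waveform as a sequence of segments: background, a bright
#' step followed by a dark step, an accelerating sinusoidal frequency sweep at
#' full contrast, and an amplitude (contrast) sweep at a fixed carrier
#' frequency, separated by background gaps. Intensities use the convention
#' 0 = dark, 0.5 = background, 1 = bright; "full-field" means spatially
#' uniform, so only the temporal trace is generated.
#'
#' @param sampleRate sampling rate of the generated trace, Hz.
#' @param nReps number of identical repetitions.
#' @param durations named numeric of segment durations in s:
#'   `baseline`, `step_on`, `step_off`, `gap1`, `freq_sweep`, `gap2`,
#'   `amp_sweep`, `tail`.
#' @param freqRange frequency sweep range in Hz (linear sweep).
#' @param ampFreq carrier frequency of the amplitude sweep, Hz.
#' @return a [ChirpStimulus-class]
#' @examples
#' ch <- makeChirp()
#' range(ch@trace)
#' @export
makeChirp <- function(sampleRate = 100, nReps = 5L,
                      durations = c(baseline = 2, step_on = 3, step_off = 3,
                                    gap1 = 2, freq_sweep = 8, gap2 = 3,
                                    amp_sweep = 8, tail = 3),
                      freqRange = c(0.5, 8), ampFreq = 2) {
  if (sampleRate <= 0) stop("sampleRate must be positive")
  if (nReps < 1) stop("nReps must be >= 1")
  need <- c("baseline", "step_on", "step_off", "gap1", "freq_sweep",
            "gap2", "amp_sweep", "tail")
  if (!all(need %in% names(durations)))
    stop("durations must name all segments: ", paste(need, collapse = ", "))
  if (any(durations <= 0)) stop("all segment durations must be positive")

  nsamp <- function(d) round(d * sampleRate)
  seg_t <- function(d) (seq_len(nsamp(d)) - 1) / sampleRate

  bg <- 0.5
  f0 <- freqRange[1]; f1 <- freqRange[2]
  d <- durations
  tf <- seg_t(d[["freq_sweep"]])
  # instantaneous phase of a linear frequency sweep
  phase <- 2 * pi * (f0 * tf + (f1 - f0) * tf^2 / (2 * d[["freq_sweep"]]))
  ta <- seg_t(d[["amp_sweep"]])
  amp <- ta / d[["amp_sweep"]]

  one <- c(rep(bg, nsamp(d[["baseline"]])),
           rep(1, nsamp(d[["step_on"]])),
           rep(0, nsamp(d[["step_off"]])),
           rep(bg, nsamp(d[["gap1"]])),
           bg + 0.5 * sin(phase),
           rep(bg, nsamp(d[["gap2"]])),
           bg + 0.5 * amp * sin(2 * pi * ampFreq * ta),
           rep(bg, nsamp(d[["tail"]])))
  one <- pmin(pmax(one, 0), 1)

  period <- length(one) / sampleRate
  new("ChirpStimulus",
      sampleRate = sampleRate,
      trace = rep(one, nReps),
      triggerTimes = (seq_len(nReps) - 1) * period,
      nReps = as.integer(nReps),
      segments = data.frame(name = need, duration = as.numeric(d[need])))
}

#' Chirp repetition duration in seconds
#' @param chirp a [ChirpStimulus-class]
#' @return duration of one repetition, s
#' @export
chirpPeriod <- function(chirp) {
  length(chirp@trace) / chirp@nReps / chirp@sampleRate
}

#' Generate the moving-bar stimulus
#'
#' One sweep per direction per repetition, directions 0, 45, ..., 315
#' degrees in seeded-random order within each repetition, separated by a
#' background gap. The sweep duration is the time for the bar to fully
#' traverse the field plus its own width.
#'
#' @param fieldExtent extent of the traversed field in mm.
#' @param speed bar speed in mm/s.
#' @param barSize bar c(width, length) in mm.
#' @param nReps number of repetitions.
#' @param gapDuration inter-trial gap at background, s.
#' @param nDirections number of directions; must be 8.
#' @param seed integer seed for the per-repetition direction order.
#' @return a [MovingBarStimulus-class]
#' @examples
#' mb <- makeMovingBar(fieldExtent = 1, seed = 1)
#' mb@sweepDuration  # (1 + 0.3) mm at 1 mm/s
#' @export
makeMovingBar <- function(fieldExtent = 1, speed = 1, barSize = c(0.3, 1),
                          nReps = 4L, gapDuration = 1, nDirections = 8L,
                          seed = 1L) {
  if (fieldExtent <= 0) stop("fieldExtent must be positive")
  if (speed <= 0) stop("speed must be positive")
  if (nDirections != 8L)
    stop("exactly 8 directions are required (45 degree spacing)")
  directions <- seq(0, 315, by = 45)
  sweep <- (fieldExtent + barSize[1]) / speed
  trial <- sweep + gapDuration

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  trialOrder <- t(vapply(seq_len(nReps), function(r) sample.int(8L),
                         integer(8L)))
  new("MovingBarStimulus",
      directions = directions,
      speed = speed,
      barSize = barSize,
      fieldExtent = fieldExtent,
      nReps = as.integer(nReps),
      trialOrder = trialOrder,
      triggerTimes = (seq_len(8L * nReps) - 1) * trial,
      sweepDuration = sweep,
      gapDuration = gapDuration)
}

#' Generate the shifted dense-noise stimulus
#'
#' Independent balanced binary frames on a coarse check grid, with the whole
#' frame jittered by a random offset on a fine sub-grid (10 um by default)
#' each frame. Balancing is exact: each frame contains as close to half
#' bright checks as possible, in randomized positions.
#'
#' @param grid number of checks c(nx, ny).
#' @param checkSize check edge length, um.
#' @param frameRate frame rate, Hz.
#' @param duration stimulus duration, s.
#' @param shiftGrid shift sub-grid resolution, um; offsets are drawn
#'   uniformly from the multiples of `shiftGrid` within one check.
#' @param seed integer seed (required).
#' @return a [ShiftedDenseNoise-class]
#' @examples
#' sn <- makeShiftedDenseNoise(duration = 10, seed = 1)
#' dim(sn@frames)  # 20 x 15 x 50
#' @export
makeShiftedDenseNoise <- function(grid = c(20L, 15L), checkSize = 40,
                                  frameRate = 5, duration = 300,
                                  shiftGrid = 10, seed) {
  if (missing(seed)) stop("seed must be given")
  if (any(grid <= 0) || checkSize <= 0 || frameRate <= 0 || duration <= 0)
    stop("grid, check size, rate and duration must all be positive")
  nf <- round(duration * frameRate)
  nchk <- prod(grid)
  nOn <- floor(nchk / 2)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  frames <- array(0L, dim = c(grid[1], grid[2], nf))
  for (f in seq_len(nf)) {
    v <- integer(nchk)
    # exactly balanced frame (nOn or nOn+1 bright checks)
    v[sample.int(nchk, nOn + rbinom(1, 1, 0.5))] <- 1L
    frames[, , f] <- v
  }
  nsteps <- max(1L, floor(checkSize / shiftGrid))
  shiftOffsets <- cbind(
    sample.int(nsteps, nf, replace = TRUE) - 1L,
    sample.int(nsteps, nf, replace = TRUE) - 1L) * shiftGrid

  new("ShiftedDenseNoise",
      grid = as.integer(grid), checkSize = checkSize,
      frameRate = frameRate, duration = duration,
      frames = frames, shiftOffsets = shiftOffsets,
      shiftGrid = shiftGrid, seed = as.integer(seed))
}

#' Rasterize shifted noise frames onto a fine pixel grid
#'
#' Resolves each frame of a [ShiftedDenseNoise-class] onto a regular pixel
#' grid after applying the frame's shift offset, so that the stimulus and the
#' receptive-field model live on a common spatial grid. Each pixel carries
#' the intensity of the check covering its center. The pixel grid is centered
#' on the stimulus center; pixels outside the (shifted) checker field take
#' the background value 0.5.
#'
#' @param stim a [ShiftedDenseNoise-class]
#' @param targetGrid pixel counts c(dx, dy); default the RF grid (32, 20).
#' @param pixelSize pixel edge length in um; default [RF_PIXEL_UM].
#' @return numeric array (dx, dy, nFrames)
#' @examples
#' sn <- makeShiftedDenseNoise(duration = 2, seed = 1)
#' fr <- rasterizeNoise(sn, targetGrid = c(20, 15), pixelSize = 40)
#' @export
rasterizeNoise <- function(stim, targetGrid = c(32L, 20L),
                           pixelSize = RF_PIXEL_UM) {
  nx <- stim@grid[1]; ny <- stim@grid[2]; cs <- stim@checkSize
  stimW <- nx * cs; stimH <- ny * cs
  dx <- targetGrid[1]; dy <- targetGrid[2]
  if (dx * pixelSize > stimW + cs || dy * pixelSize > stimH + cs)
    stop("target grid does not fit inside the stimulus extent")
  # pixel centers, stimulus-centered coordinates (um), origin top-left
  px <- (seq_len(dx) - 0.5) * pixelSize - dx * pixelSize / 2
  py <- (seq_len(dy) - 0.5) * pixelSize - dy * pixelSize / 2
  nf <- dim(stim@frames)[3]
  out <- array(0.5, dim = c(dx, dy, nf))
  for (f in seq_len(nf)) {
    # the whole checker field is translated by the frame's offset
    ix <- floor((px - stim@shiftOffsets[f, 1] + stimW / 2) / cs) + 1L
    iy <- floor((py - stim@shiftOffsets[f, 2] + stimH / 2) / cs) + 1L
    okx <- ix >= 1L & ix <= nx
    oky <- iy >= 1L & iy <= ny
    fr <- stim@frames[, , f]
    sub <- fr[ix[okx], iy[oky], drop = FALSE]
    out[okx, oky, f] <- sub
  }
  out
}

## RNG state helpers: seeded generators must not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
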