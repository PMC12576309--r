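#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Constants shared across the package ---------------------------------------

#' Recording and analysis constants
#'
#' Scan rate of the two-photon recording grid (Hz), the fine-grid pixel size
#' used for receptive-field estimation (micrometers per pixel), and the fixed
#' super-group labels of the functional RGC taxonomy.
#'
#' @format `RECORDING_RATE_HZ` is 7.8125 Hz (64 x 64 pixel scans);
#'   `RF_PIXEL_UM` is 12.5 um/px for the (32, 20) receptive-field grid;
#'   `SUPER_GROUPS` is a character vector of length five.
#' @name constants
NULL

#' @rdname constants
#' @export
RECORDING_RATE_HZ <- 7.8125

#' @rdname constants
#' @export
RF_PIXEL_UM <- 12.5

#' @rdname constants
#' @export
SUPER_GROUPS <- c("Off", "On-Off", "Fast On", "Slow On", "Uncertain")

#' @rdname constants
#' @export
AGES <- c("P30", "P45", "P90", "P180")

## ChirpStimulus --------------------------------------------------------------

#' Full-field chirp stimulus
#'
#' A spatially uniform "fingerprinting" stimulus combining a bright/dark step,
#' an accelerating frequency sweep and an amplitude (contrast) sweep, used to
#' characterize the temporal response profile of ganglion-cell-layer cells.
#' Intensity is unitless in \[0, 1\] with 0 = dark, 0.5 = background,
#' 1 = bright.
#'
#' @slot sampleRate sampling rate of `trace` in Hz.
#' @slot trace intensity per sample for all repetitions concatenated.
#' @slot triggerTimes start time (s) of each repetition.
#' @slot nReps number of repetitions.
#' @slot segments data.frame describing the waveform segments
#'   (name, duration in s).
#' @seealso [makeChirp()]
#' @export
setClass("ChirpStimulus",
  representation(
    sampleRate = "numeric",
    trace = "numeric",
    triggerTimes = "numeric",
    nReps = "integer",
    segments = "data.frame"
  )
)

setValidity("ChirpStimulus", function(object) {
  msg <- NULL
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (any(!is.finite(object@trace)))
    msg <- c(msg, "trace must be finite")
  if (length(object@trace) &&
      (min(object@trace) < 0 || max(object@trace) > 1))
    msg <- c(msg, "intensities must lie in [0, 1]")
  if (object@nReps < 1L)
    msg <- c(msg, "nReps must be >= 1")
  if (length(object@triggerTimes) != object@nReps)
    msg <- c(msg, "one trigger time per repetition required")
  if (length(object@trace) == 0L)
    msg <- c(msg, "trace must be non-empty (duration > 0)")
  # repetitions must be sample-for-sample identical
  if (object@nReps > 1L && length(object@trace) %% object@nReps == 0L) {
    per <- length(object@trace) %/% object@nReps
    reps <- matrix(object@trace, nrow = per)
    if (max(abs(reps - reps[, 1])) > 0)
      msg <- c(msg, "repetitions must be bit-identical")
  }
  if (is.null(msg)) TRUE else msg
})

## MovingBarStimulus ----------------------------------------------------------

#' Moving-bar stimulus
#'
#' A bright bar (0.3 x 1 mm by default) sweeping across the recording field at
#' 1 mm/s in eight directions spaced 45 degrees, each direction presented once
#' per repetition in seeded-random order. The bar is represented by its
#' trial timing (direction, trigger), which is what the trace simulator and
#' the snippeting step consume; no pixel rendering is kept.
#'
#' @slot directions the eight motion directions in degrees.
#' @slot speed bar speed in mm/s.
#' @slot barSize bar width and length in mm.
#' @slot fieldExtent extent of the traversed field in mm.
#' @slot nReps number of repetitions (each covering all 8 directions).
#' @slot trialOrder integer matrix (nReps x 8) of direction indices.
#' @slot triggerTimes trial start times in s (one per trial).
#' @slot sweepDuration duration of one sweep in s.
#' @slot gapDuration inter-trial background gap in s.
#' @seealso [makeMovingBar()]
#' @export
setClass("MovingBarStimulus",
  representation(
    directions = "numeric",
    speed = "numeric",
    barSize = "numeric",
    fieldExtent = "numeric",
    nReps = "integer",
    trialOrder = "matrix",
    triggerTimes = "numeric",
    sweepDuration = "numeric",
    gapDuration = "numeric"
  )
)

setValidity("MovingBarStimulus", function(object) {
  msg <- NULL
  d <- sort(object@directions %% 360)
  if (length(d) != 8L || any(abs(diff(d) - 45) > 1e-9))
    msg <- c(msg, "exactly 8 distinct directions spaced 45 degrees required")
  if (object@speed <= 0) msg <- c(msg, "speed must be positive")
  if (any(apply(object@trialOrder, 1, function(r) !setequal(r, 1:8))))
    msg <- c(msg, "each repetition must contain every direction exactly once")
  if (length(object@triggerTimes) != 8L * object@nReps)
    msg <- c(msg, "one trigger per trial required")
  if (is.null(msg)) TRUE else msg
})

## ShiftedDenseNoise ----------------------------------------------------------

#' Shifted dense-noise stimulus
#'
#' Balanced binary checkerboard (20 x 15 checks of 40 um, 5 Hz, 5 min by
#' default) whose whole frame is jittered on a 10 um sub-grid each frame,
#' improving the spatial resolution of receptive-field mapping beyond the
#' check size.
#'
#' @slot grid number of checks c(nx, ny).
#' @slot checkSize check edge length in um.
#' @slot frameRate frame rate in Hz.
#' @slot duration stimulus duration in s.
#' @slot frames integer array (nx, ny, nFrames) with values in \{0, 1\}.
#' @slot shiftOffsets integer matrix (nFrames x 2) of frame shifts in um,
#'   multiples of `shiftGrid`.
#' @slot shiftGrid shift sub-grid resolution in um.
#' @slot seed integer seed the frames were drawn with.
#' @seealso [makeShiftedDenseNoise()], [rasterizeNoise()]
#' @export
setClass("ShiftedDenseNoise",
  representation(
    grid = "integer",
    checkSize = "numeric",
    frameRate = "numeric",
    duration = "numeric",
    frames = "array",
    shiftOffsets = "matrix",
    shiftGrid = "numeric",
    seed = "integer"
  )
)

setValidity("ShiftedDenseNoise", function(object) {
  msg <- NULL
  nf <- round(object@duration * object@frameRate)
  if (dim(object@frames)[3] != nf)
    msg <- c(msg, "frame count must equal duration x frame_rate")
  if (!all(object@frames %in% c(0L, 1L)))
    msg <- c(msg, "frames must be binary {0,1}")
  if (nrow(object@shiftOffsets) != dim(object@frames)[3])
    msg <- c(msg, "one shift offset pair per frame required")
  if (any(object@shiftOffsets %% object@shiftGrid != 0))
    msg <- c(msg, "shift offsets must be multiples of the shift grid")
  pm <- apply(object@frames, 3, mean)
  if (any(pm < 0.4 - 1e-12 | pm > 0.6 + 1e-12))
    msg <- c(msg, "per-frame mean must lie in [0.4, 0.6] (balanced)")
  if (is.null(msg)) TRUE else msg
})

## TypeLibrary ----------------------------------------------------------------

#' Library of functional RGC type templates
#'
#' Thirty-two synthetic response templates spanning the five functional
#' super-groups (Off, On-Off, Fast On, Slow On, Uncertain). Each template
#' holds peak-normalized chirp and moving-bar response time courses (already
#' in calcium-indicator space), direction/orientation-selectivity flags and
#' tuning parameters, a ground-truth spatio-temporal receptive-field
#' parameterization, a soma-size distribution and a baseline abundance.
#' The templates are synthetic stand-ins for the reference taxonomy the
#' published classifier was trained on; they are generated, not measured.
#'
#' @slot templates list of 32 template parameter lists (see
#'   [makeTypeLibrary()] for fields).
#' @slot abundance named numeric of baseline type fractions (sums to 1).
#' @slot sampleRate rate (Hz) of the template time courses.
#' @slot seed seed used to generate the library.
#' @export
setClass("TypeLibrary",
  representation(
    templates = "list",
    abundance = "numeric",
    sampleRate = "numeric",
    seed = "integer"
  )
)

setValidity("TypeLibrary", function(object) {
  msg <- NULL
  if (length(object@templates) != 32L)
    msg <- c(msg, "32 templates required")
  if (abs(sum(object@abundance) - 1) > 1e-12)
    msg <- c(msg, "baseline abundances must sum to 1")
  pk <- vapply(object@templates,
               function(tp) max(abs(tp$chirp_template)), numeric(1))
  if (any(abs(pk - 1) > 1e-9))
    msg <- c(msg, "chirp templates must be peak-normalized to 1")
  lag <- vapply(object@templates, function(tp) tp$peak_lag_s, numeric(1))
  if (any(lag <= 0 | lag >= 0.3))
    msg <- c(msg, "temporal-kernel peak lags must lie in (0, 0.3) s")
  sg <- vapply(object@templates, function(tp) tp$super_group, character(1))
  if (!all(SUPER_GROUPS %in% sg))
    msg <- c(msg, "all five super-groups must be represented")
  if (is.null(msg)) TRUE else msg
})

## DegenerationSchedule -------------------------------------------------------

#' Degeneration schedule
#'
#' Per-(super-group, age) multipliers describing how photoreceptor
#' degeneration attenuates RGC responsiveness, plus scalar perturbations of
#' receptive-field size and temporal kinetics. The wild-type schedule is
#' identically 1. Responsiveness multipliers must be non-increasing with age
#' within each super-group.
#'
#' @slot multipliers numeric matrix (5 super-groups x 4 ages), values in
#'   \[0, 1\], applied to the baseline responsive probability.
#' @slot rfSizeScale numeric matrix, multiplicative scale on ground-truth
#'   RF sigma.
#' @slot kineticsScale numeric matrix, multiplicative scale on the temporal
#'   kernel peak lag (values < 1 mean faster kinetics).
#' @slot noiseScale numeric matrix, multiplicative scale on trace noise.
#' @seealso [degenerationSchedule()]
#' @export
setClass("DegenerationSchedule",
  representation(
    multipliers = "matrix",
    rfSizeScale = "matrix",
    kineticsScale = "matrix",
    noiseScale = "matrix"
  )
)

setValidity("DegenerationSchedule", function(object) {
  msg <- NULL
  for (sl in c("multipliers", "rfSizeScale", "kineticsScale", "noiseScale")) {
    m <- slot(object, sl)
    if (!identical(rownames(m), SUPER_GROUPS) ||
        !identical(colnames(m), AGES))
      msg <- c(msg, sprintf("%s must be a 5 x 4 matrix with super-group rows and age columns", sl))
  }
  m <- object@multipliers
  if (any(m < 0 | m > 1))
    msg <- c(msg, "responsiveness multipliers must lie in [0, 1]")
  if (any(t(apply(m, 1, diff)) > 1e-12))
    msg <- c(msg, "responsiveness multipliers must be non-increasing with age")
  if (is.null(msg)) TRUE else msg
})

## RGCCohort ------------------------------------------------------------------

#' A cohort of recorded or simulated ganglion-cell-layer cells
#'
#' Container for per-cell raw fluorescence traces (one matrix per stimulus,
#' time samples x cells, on the 7.8125 Hz recording grid), the stimulus
#' trigger logs, and per-cell metadata (genotype, age, field, soma size and -
#' for simulated cohorts - the ground truth).
#'
#' @slot traces named list of numeric matrices (time x cells), one per
#'   stimulus ("chirp", "bar", "noise").
#' @slot triggers named list of numeric trigger-time vectors (s), shared by
#'   all cells of the cohort.
#' @slot sampleRate recording rate in Hz.
#' @slot cellData a [S4Vectors::DataFrame] with one row per cell.
#' @slot stimuli named list of the stimulus objects presented.
#' @seealso [simulateCohort()]
#' @export
setClass("RGCCohort",
  representation(
    traces = "list",
    triggers = "list",
    sampleRate = "numeric",
    cellData = "DataFrame",
    stimuli = "list"
  )
)

setValidity("RGCCohort", function(object) {
  msg <- NULL
  n <- nrow(object@cellData)
  for (nm in names(object@traces)) {
    tr <- object@traces[[nm]]
    if (!is.matrix(tr) || ncol(tr) != n)
      msg <- c(msg, sprintf("traces$%s must be a time x cells matrix with %d columns", nm, n))
    else if (any(!is.finite(tr)))
      msg <- c(msg, sprintf("traces$%s must be finite", nm))
  }
  if (!all(names(object@traces) %in% names(object@triggers)))
    msg <- c(msg, "every stimulus with traces needs a trigger log")
  if (!is.null(object@cellData$soma_size) &&
      any(object@cellData$soma_size <= 0))
    msg <- c(msg, "soma sizes must be positive")
  if (is.null(msg)) TRUE else msg
})

## SplineBasis ----------------------------------------------------------------

#' Tensor cubic B-spline basis for receptive-field estimation
#'
#' Maps a compact coefficient vector b (kx * ky * ktau entries) to a
#' spatio-temporal receptive field F(x, y, tau) = S b on the fixed evaluation
#' grid, with the default (kx, ky, ktau) = (10, 12, 9) and grid
#' (dx, dy, dtau) = (32, 20, 15).
#'
#' @slot dims evaluation grid dimensions c(dx, dy, dtau).
#' @slot knots coefficients per axis c(kx, ky, ktau).
#' @slot Sx,Sy,St per-axis basis matrices (dx x kx etc.).
#' @seealso [splineBasis()], [assembleRF()]
#' @export
setClass("SplineBasis",
  representation(
    dims = "integer",
    knots = "integer",
    Sx = "matrix",
    Sy = "matrix",
    St = "matrix"
  )
)

setValidity("SplineBasis", function(object) {
  msg <- NULL
  ok <- identical(dim(object@Sx), c(object@dims[1], object@knots[1])) &&
    identical(dim(object@Sy), c(object@dims[2], object@knots[2])) &&
    identical(dim(object@St), c(object@dims[3], object@knots[3]))
  if (!ok) msg <- c(msg, "axis basis matrices must match dims x knots")
  for (m in list(object@Sx, object@Sy, object@St))
    if (qr(m)$rank < ncol(m))
      msg <- c(msg, "basis columns must be linearly independent")
  if (is.null(msg)) TRUE else msg
})

## RFModel --------------------------------------------------------------------

#' Fitted spatio-temporal receptive field
#'
#' Result of the spline-basis penalized linear-Gaussian fit for one cell:
#' coefficients, the assembled and smoothed RF, its rank-1 SVD split into
#' temporal and spatial components, the 2D Gaussian fit of the spatial
#' component, derived size/kinetics measures and the quality gates.
#'
#' @slot coef spline coefficient vector b.
#' @slot intercept fitted intercept y0 (rate units).
#' @slot basis the [SplineBasis-class] used.
#' @slot F smoothed spatio-temporal RF, array (dx, dy, dtau).
#' @slot Ft temporal component, scaled so max |Ft| = 1.
#' @slot Fs spatial component, scaled so max |Fs| = max |F|.
#' @slot lags lag axis in s (positive = stimulus preceding response).
#' @slot gauss named list of the 2D Gaussian fit (amplitude, x0, y0,
#'   sigma_x, sigma_y in px and um, theta), or empty if the fit failed.
#' @slot rfSize named list: `area_um2`, `diameter_um` (2-SD ellipse,
#'   smoothing-corrected) and uncorrected `diameter_raw_um`.
#' @slot mainPeakLag main temporal peak lag in s (NA if no qualifying peak).
#' @slot qiSvd,qiSrf,qiTrf quality indices in \[0, 1\].
#' @slot passesQuality logical, the overall RF quality gate.
#' @slot fit list with optimizer diagnostics (loss trace, steps).
#' @export
setClass("RFModel",
  representation(
    coef = "numeric",
    intercept = "numeric",
    basis = "SplineBasis",
    F = "array",
    Ft = "numeric",
    Fs = "matrix",
    lags = "numeric",
    gauss = "list",
    rfSize = "list",
    mainPeakLag = "numeric",
    qiSvd = "numeric",
    qiSrf = "numeric",
    qiTrf = "numeric",
    passesQuality = "logical",
    fit = "list"
  )
)

setValidity("RFModel", function(object) {
  msg <- NULL
  if (length(object@Ft) && max(abs(object@F)) > 0 &&
      abs(max(abs(object@Ft)) - 1) > 1e-9)
    msg <- c(msg, "temporal component must satisfy max|Ft| = 1")
  for (q in c(object@qiSvd, object@qiSrf))
    if (!is.na(q) && (q < 0 || q > 1))
      msg <- c(msg, "reported quality indices must be clipped to [0, 1]")
  if (is.null(msg)) TRUE else msg
})
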