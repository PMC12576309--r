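## Forward simulation of GCL populations: linear-nonlinear-calcium response
## model, slow drift, white noise, degeneration schedule.

.biphasicKernel <- function(peakLag, fs, len = 0.6) {
  # unit-peak biphasic temporal kernel: fast positive lobe at peakLag,
  # slower negative rebound
  tt <- seq(0, len, by = 1 / fs)
  k <- (tt / peakLag) * exp(1 - tt / peakLag) -
    0.55 * (tt / (2.2 * peakLag)) * exp(1 - tt / (2.2 * peakLag))
  k / max(abs(k))
}

.calciumKernel <- function(fs, tau = 0.5) {
  tt <- seq(0, 5 * tau, by = 1 / fs)
  k <- exp(-tt / tau)
  k / sum(k)
}

.convCausal <- function(x, k) {
  # causal convolution: out[t] = sum_i k[i] x[t - i + 1]
  n <- length(x)
  xp <- c(numeric(length(k)), x)   # zero history before the sequence
  out <- as.numeric(stats::filter(xp, k, method = "convolution", sides = 1))
  out[length(k) + seq_len(n)]
}

.tuningFactor <- function(theta, template) {
  pref <- template$preferred_angle * pi / 180
  th <- theta * pi / 180
  k <- template$tuning_kappa
  if (template$ds_flag) {
    exp(k * (cos(th - pref) - 1))
  } else if (template$os_flag) {
    exp(k * (cos(2 * (th - pref)) - 1))
  } else {
    1 + 0.04 * cos(th - pref)   # weak residual anisotropy
  }
}

.slowDrift <- function(n, fs, amplitude = 0.3) {
  # sum of two slow sinusoids (periods >= 45 s) with random phases
  tt <- (seq_len(n) - 1) / fs
  amplitude * (sin(2 * pi * tt / 90 + runif(1, 0, 2 * pi)) +
               0.6 * sin(2 * pi * tt / 45 + runif(1, 0, 2 * pi)))
}

#' Simulate the recording of a single GCL cell
#'
#' Generates raw fluorescence traces for one cell from its type template
#' under the linear-nonlinear-calcium response model: chirp and moving-bar
#' responses follow the template time course (with per-repetition gain
#' jitter and, for the bar, a direction tuning factor), and the dense-noise
#' response is rate(t) = max(0, RF (*) stimulus) from the cell's ground-truth
#' separable spatio-temporal receptive field. Rates are convolved with a
#' single-exponential calcium kernel, and a slow additive drift
#' (time constants >= 45 s), a constant baseline and white noise are added.
#'
#' Traces start with `baselineDur` seconds of stimulus-free recording, as in
#' the acquisition protocol, so the trigger logs are offset accordingly.
#'
#' @param template one template list from a [TypeLibrary-class]
#' @param chirp,bar the stimulus objects; either may be NULL to skip.
#' @param noise a [ShiftedDenseNoise-class] or NULL to skip.
#' @param noiseScale standard deviation of the additive white noise, in
#'   units of the (unit) template peak amplitude.
#' @param responsive logical; if FALSE only baseline, drift and noise are
#'   generated.
#' @param rfSizeScale,kineticsScale multiplicative perturbations of the
#'   ground-truth RF sigma and temporal-kernel peak lag (degeneration).
#' @param sampleRate recording rate, Hz.
#' @param baselineDur stimulus-free head recording, s.
#' @param seed integer seed.
#' @return list with `traces` (named list of numeric vectors), `triggers`
#'   (named list, s), and `ground_truth` (realized RF parameters).
#' @export
simulateCell <- function(template, chirp = NULL, bar = NULL, noise = NULL,
                         noiseScale = 0.25, responsive = TRUE,
                         rfSizeScale = 1, kineticsScale = 1,
                         sampleRate = RECORDING_RATE_HZ,
                         baselineDur = 20, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  fs <- sampleRate
  # all stochastic perturbations scale together with noiseScale, so a
  # noiseless cell (noiseScale = 0) is perfectly repeatable
  driftAmp <- 0.3 * noiseScale / 0.25
  gainSd <- 0.1 * noiseScale / 0.25
  traces <- list(); triggers <- list()
  gt <- list(group_id = template$group_id, responsive = responsive)

  if (!is.null(chirp)) {
    per <- chirpPeriod(chirp)
    nTot <- ceiling((baselineDur + chirp@nReps * per) * fs) + 4L
    sig <- numeric(nTot)
    if (responsive) {
      tmpl <- template$chirp_template
      for (r in seq_len(chirp@nReps)) {
        i0 <- round((baselineDur + (r - 1) * per) * fs)
        gain <- exp(rnorm(1, 0, gainSd))
        idx <- i0 + seq_along(tmpl)
        sig[idx] <- sig[idx] + gain * tmpl
      }
    }
    traces$chirp <- sig
    triggers$chirp <- baselineDur + chirp@triggerTimes
  }

  if (!is.null(bar)) {
    trial <- bar@sweepDuration + bar@gapDuration
    nTrials <- length(bar@triggerTimes)
    nTot <- ceiling((baselineDur + nTrials * trial) * fs) + 4L
    sig <- numeric(nTot)
    if (responsive) {
      tmpl <- template$bar_template
      dirs <- bar@directions[as.vector(t(bar@trialOrder))]
      for (j in seq_len(nTrials)) {
        i0 <- round((baselineDur + bar@triggerTimes[j]) * fs)
        amp <- .tuningFactor(dirs[j], template) * exp(rnorm(1, 0, gainSd))
        idx <- i0 + seq_along(tmpl)
        sig[idx] <- sig[idx] + amp * tmpl
      }
    }
    traces$bar <- sig
    triggers$bar <- baselineDur + bar@triggerTimes
    gt$directions <- bar@directions[as.vector(t(bar@trialOrder))]
  }

  if (!is.null(noise)) {
    fsUp <- 10 * noise@frameRate
    sig0 <- if (responsive) {
      sx <- template$rf_sigma_um[1] * rfSizeScale
      sy <- template$rf_sigma_um[2] * rfSizeScale
      lagPk <- template$peak_lag_s * kineticsScale
      # RF center within the central region covered by the fine grid
      cx <- runif(1, -100, 100); cy <- runif(1, -50, 50)
      pol <- if (template$rf_polarity == 0) sample(c(-1, 1), 1) else
        template$rf_polarity
      gt$rf <- list(center_um = c(cx, cy), sigma_um = c(sx, sy),
                    polarity = pol, peak_lag_s = lagPk)
      frames <- rasterizeNoise(noise)
      dx <- dim(frames)[1]; dy <- dim(frames)[2]
      px <- (seq_len(dx) - 0.5) * RF_PIXEL_UM - dx * RF_PIXEL_UM / 2
      py <- (seq_len(dy) - 0.5) * RF_PIXEL_UM - dy * RF_PIXEL_UM / 2
      spat <- pol * outer(exp(-(px - cx)^2 / (2 * sx^2)),
                          exp(-(py - cy)^2 / (2 * sy^2)))
      spat <- spat / sum(abs(spat))
      # spatial projection per frame (contrast-coded), upsampled x10 (ZOH),
      # then temporal convolution at 50 Hz, rectification, calcium kernel
      proj <- apply(frames - 0.5, 3, function(fr) sum(fr * spat))
      projUp <- rep(proj, each = 10L)
      kt <- .biphasicKernel(lagPk, fsUp)
      rate <- pmax(0, .convCausal(projUp, kt))
      ca <- .convCausal(rate, .calciumKernel(fsUp))
      # resample to the recording grid, amplitude-normalized to unit peak
      nRec <- ceiling(noise@duration * fs)
      r <- stats::approx(x = (seq_along(ca) - 1) / fsUp, y = ca,
                         xout = (seq_len(nRec) - 1) / fs, rule = 2)$y
      if (max(abs(r)) > 0) r <- r / max(abs(r))
      r
    } else numeric(ceiling(noise@duration * fs))
    nTot <- ceiling(baselineDur * fs) + length(sig0)
    sig <- c(numeric(ceiling(baselineDur * fs)), sig0)
    traces$noise <- sig
    triggers$noise <- baselineDur
  }

  for (nm in names(traces)) {
    n <- length(traces[[nm]])
    traces[[nm]] <- 1 + traces[[nm]] + .slowDrift(n, fs, driftAmp) +
      rnorm(n, 0, noiseScale)
  }
  list(traces = traces, triggers = triggers, ground_truth = gt)
}

#' Simulate a cohort of recording fields
#'
#' Draws fields of 100-120 GCL cells each. Per cell, a functional type is
#' drawn from the library's baseline abundances, the cell is responsive with
#' probability `baseResponsive` times the schedule's responsiveness
#' multiplier for its (super-group, age), its soma size is drawn from the
#' type's log-normal distribution, and its traces are simulated with
#' [simulateCell()] under the schedule's RF perturbations. Non-responsive
#' cells get noise-plus-drift-only traces.
#'
#' @param genotype "wt" or "rd10".
#' @param age one of "P30", "P45", "P90", "P180".
#' @param library a [TypeLibrary-class]; default built from `seed`.
#' @param schedule a [DegenerationSchedule-class]; default
#'   `degenerationSchedule(genotype)`.
#' @param nFields number of recording fields.
#' @param seed integer seed; all randomness flows from it.
#' @param stimuli character subset of c("chirp", "bar", "noise") to present;
#'   the noise stimulus is the expensive one and is only simulated when
#'   receptive-field estimation is intended.
#' @param noiseScale white-noise standard deviation (template peak = 1).
#' @param baseResponsive baseline responsive probability (wild-type).
#' @param fieldSizeRange per-field cell count range, drawn uniformly.
#' @return an [RGCCohort-class] whose `cellData` carries the ground truth
#'   columns `gt_group`, `gt_super_group`, `gt_responsive`.
#' @examples
#' lib <- makeTypeLibrary(seed = 1)
#' coh <- simulateCohort("wt", "P30", library = lib, nFields = 1, seed = 1,
#'                       stimuli = "chirp")
#' coh
#' @export
simulateCohort <- function(genotype = c("wt", "rd10"),
                           age = AGES,
                           library = makeTypeLibrary(seed),
                           schedule = degenerationSchedule(genotype),
                           nFields = 3L, seed = 1L,
                           stimuli = c("chirp", "bar"),
                           noiseScale = 0.25,
                           baseResponsive = 0.6,
                           fieldSizeRange = c(100L, 120L)) {
  genotype <- match.arg(genotype)
  age <- match.arg(age)
  stimuli <- match.arg(stimuli, c("chirp", "bar", "noise"),
                       several.ok = TRUE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  chirp <- if ("chirp" %in% stimuli) makeChirp() else NULL
  bar <- if ("bar" %in% stimuli) makeMovingBar(seed = seed) else NULL
  noise <- if ("noise" %in% stimuli)
    makeShiftedDenseNoise(seed = seed) else NULL

  mult <- schedule@multipliers[, age]
  rows <- list(); traceCols <- list()
  cellSeeds <- integer(0)
  sizes <- seq(fieldSizeRange[1], fieldSizeRange[2])
  for (f in seq_len(nFields)) {
    nc <- sizes[sample.int(length(sizes), 1)]
    for (i in seq_len(nc)) {
      g <- sample.int(32L, 1, prob = library@abundance)
      tp <- library@templates[[g]]
      sg <- tp$super_group
      resp <- runif(1) < baseResponsive * mult[[sg]]
      soma <- stats::rlnorm(1, log(tp$soma_mean), tp$soma_sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("%s_%s_f%02d_c%03d", genotype, age, f, i),
        field_id = sprintf("%s_%s_f%02d", genotype, age, f),
        genotype = genotype, age = age, soma_size = soma,
        gt_group = g, gt_super_group = sg, gt_responsive = resp,
        stringsAsFactors = FALSE)
      cellSeeds <- c(cellSeeds, sample.int(.Machine$integer.max, 1))
      cell <- simulateCell(
        tp, chirp = chirp, bar = bar, noise = noise,
        noiseScale = noiseScale * schedule@noiseScale[sg, age],
        responsive = resp,
        rfSizeScale = schedule@rfSizeScale[sg, age],
        kineticsScale = schedule@kineticsScale[sg, age],
        seed = cellSeeds[length(cellSeeds)])
      traceCols[[length(traceCols) + 1L]] <- cell
    }
  }

  cd <- do.call(rbind, rows)
  trc <- list(); trg <- list()
  for (nm in intersect(c("chirp", "bar", "noise"), stimuli)) {
    trc[[nm]] <- vapply(traceCols, function(cc) cc$traces[[nm]],
                        numeric(length(traceCols[[1]]$traces[[nm]])))
    trg[[nm]] <- traceCols[[1]]$triggers[[nm]]
  }
  gtRf <- lapply(traceCols, function(cc) cc$ground_truth$rf)

  cdDF <- S4Vectors::DataFrame(cd)
  cdDF$gt_rf <- gtRf
  stimList <- list()
  if (!is.null(chirp)) stimList$chirp <- chirp
  if (!is.null(bar)) stimList$bar <- bar
  if (!is.null(noise)) stimList$noise <- noise

  new("RGCCohort", traces = trc, triggers = trg,
      sampleRate = RECORDING_RATE_HZ, cellData = cdDF,
      stimuli = stimList)
}
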