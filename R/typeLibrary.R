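## Synthetic library of 32 functional RGC type templates.
##
## The published classification rests on a reference taxonomy of 32
## functional groups in five super-groups. That reference dataset is external
## prior work; here the templates are generated from the chirp/bar waveforms
## through a small linear-nonlinear response model so that every downstream
## stage (quality indexing, tuning, classification, abundance statistics) can
## be exercised with known ground truth. They are synthetic stand-ins, not
## measurements.

#' Super-group of a functional RGC group
#'
#' Fixed lookup from group id (1-32) to the five functional super-groups.
#' The mapping follows the reference taxonomy convention: groups 1-9 "Off",
#' 10-14 "On-Off", 15-20 "Fast On", 21-28 "Slow On", 29-32 "Uncertain".
#'
#' @param groupId integer vector of group ids in 1..32
#' @return character vector of super-group labels
#' @examples
#' superGroup(c(1, 17, 27, 32))
#' @export
superGroup <- function(groupId) {
  if (any(is.na(groupId)) || any(groupId < 1 | groupId > 32))
    stop("group ids must lie in 1..32")
  bins <- cut(as.integer(groupId), breaks = c(0, 9, 14, 20, 28, 32),
              labels = SUPER_GROUPS)
  as.character(bins)
}

#' Generate the synthetic type-template library
#'
#' Builds 32 response templates spanning the five super-groups. Chirp and
#' moving-bar response time courses are derived by passing the actual
#' stimulus waveforms through type-specific linear-nonlinear pathway models
#' (On/Off transient and sustained drives with per-type time constants,
#' adaptation and weights), then convolving with a single-exponential calcium
#' indicator kernel (tau = 0.5 s) and peak-normalizing. Tuning flags (DS/OS),
#' ground-truth receptive-field parameters, soma-size distributions and
#' baseline abundances are drawn once from the seed.
#'
#' @param seed integer seed; the library is a pure function of it.
#' @param sampleRate recording rate the templates are sampled at, Hz.
#' @param chirp optional [ChirpStimulus-class]; default [makeChirp()].
#' @param bar optional [MovingBarStimulus-class]; default [makeMovingBar()].
#' @param calciumTau calcium indicator decay time constant, s.
#' @return a [TypeLibrary-class]
#' @examples
#' lib <- makeTypeLibrary(seed = 1)
#' lib
#' @export
makeTypeLibrary <- function(seed = 1L, sampleRate = RECORDING_RATE_HZ,
                            chirp = makeChirp(), bar = makeMovingBar(seed = 1L),
                            calciumTau = 0.5) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  fsS <- chirp@sampleRate
  one <- chirp@trace[seq_len(length(chirp@trace) / chirp@nReps)]
  contrast <- one - 0.5

  lp <- function(x, tau, fs) {
    # first-order low-pass (discrete exponential filter)
    a <- exp(-1 / (fs * tau))
    as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  }
  caKernel <- function(fs, tau = calciumTau) {
    tt <- seq(0, 5 * tau, by = 1 / fs)
    k <- exp(-tt / tau); k / sum(k)
  }
  toCalcium <- function(rate, fs) {
    .convCausal(rate, caKernel(fs))
  }
  resample <- function(x, fsFrom, fsTo, n) {
    stats::approx(x = (seq_along(x) - 1) / fsFrom,
                  y = x, xout = (seq_len(n) - 1) / fsTo, rule = 2)$y
  }

  nChirp <- floor(chirpPeriod(chirp) * sampleRate)
  trialDur <- bar@sweepDuration + bar@gapDuration
  nBar <- floor(trialDur * sampleRate)

  # pathway drives shared by all templates (computed at the stimulus rate)
  dI <- c(0, diff(contrast)) * fsS
  tOne <- (seq_along(one) - 1) / fsS
  segDur <- chirp@segments$duration
  segStart <- cumsum(c(0, segDur))[seq_along(segDur)]
  names(segStart) <- chirp@segments$name
  # instantaneous frequency over the sweep; background elsewhere
  fInst <- rep(NA_real_, length(one))
  inSweep <- tOne >= segStart[["freq_sweep"]] &
    tOne < segStart[["freq_sweep"]] + segDur[chirp@segments$name == "freq_sweep"]
  tf <- tOne[inSweep] - segStart[["freq_sweep"]]
  fInst[inSweep] <- 0.5 + (8 - 0.5) * tf / max(tf)
  # contrast amplitude over the amplitude sweep
  aInst <- rep(NA_real_, length(one))
  inAmp <- tOne >= segStart[["amp_sweep"]] &
    tOne < segStart[["amp_sweep"]] + segDur[chirp@segments$name == "amp_sweep"]
  ta <- tOne[inAmp] - segStart[["amp_sweep"]]
  aInst[inAmp] <- ta / max(ta)

  chirpResponse <- function(p) {
    # transient pathway drives with per-type kinetics
    onT <- pmax(0, lp(dI, p$tauT, fsS))
    offT <- pmax(0, lp(-dI, p$tauT, fsS))
    onS <- pmax(0, lp(contrast, p$tauS, fsS))
    offS <- pmax(0, lp(-contrast, p$tauS, fsS))
    r <- p$wOnT * onT + p$wOffT * offT + p$wOnS * onS + p$wOffS * offS
    # frequency tuning: log-Gaussian gain around the preferred frequency
    g <- rep(1, length(r))
    g[inSweep] <- exp(-(log2(fInst[inSweep] / p$f0))^2 / (2 * p$bw^2))
    # contrast threshold: response only above the type's threshold
    g[inAmp] <- pmax(0, aInst[inAmp] - p$c0) / (1 - p$c0)
    r <- r * g
    if (p$adapt > 0) r <- pmax(0, r - p$adapt * lp(r, 1.5, fsS))
    r
  }

  # bar passage response: bumps at leading/trailing edge crossing the RF
  barResponse <- function(p) {
    tt <- (seq_len(round(trialDur * fsS)) - 1) / fsS
    tLead <- (bar@fieldExtent / 2 + bar@barSize[1] / 2) / bar@speed
    tTrail <- tLead + bar@barSize[1] / bar@speed
    bump <- function(t0, w) exp(-(tt - t0)^2 / (2 * w^2))
    p$wOn * bump(tLead, p$bumpW) + p$wOff * bump(tTrail, p$bumpW)
  }

  ## per-group pathway parameters ---------------------------------------------
  sgOf <- superGroup(1:32)
  # groups flagged DS / OS in the shipped convention (On-Off DS pair,
  # Off OS pair, one Fast On DS)
  dsGroups <- c(12L, 13L, 16L)
  osGroups <- c(1L, 2L)
  alphaGroups <- c(5L, 8L, 19L, 24L)   # large-soma (alpha-like) types

  # within-super-group index, used to spread types across the preferred-
  # frequency and contrast-threshold axes so templates are distinguishable
  sgIdx <- stats::ave(seq_len(32), sgOf, FUN = seq_along)
  sgN <- stats::ave(seq_len(32), sgOf, FUN = length)

  templates <- vector("list", 32L)
  for (g in 1:32) {
    sg <- sgOf[g]
    u <- runif(6)  # per-type variation, deterministic in the seed
    frac <- (sgIdx[g] - 0.5) / sgN[g]   # position within the super-group
    f0 <- 2^(log2(0.7) + frac * log2(7 / 0.7))  # preferred frequency, Hz
    bw <- 0.8 + 1.2 * u[5]                      # bandwidth, octaves
    c0 <- 0.5 * frac * u[6] + 0.1 * u[2]        # contrast threshold
    p <- switch(sg,
      "Off" = list(wOnT = 0.05 * u[5], wOffT = 0.6 + 0.8 * u[1],
                   wOnS = 0, wOffS = 0.6 * frac,
                   tauT = 0.04 + 0.10 * u[3], tauS = 0.3 + 0.7 * u[4],
                   adapt = 0.6 * u[6]),
      "On-Off" = list(wOnT = 0.4 + 0.8 * frac, wOffT = 1.2 - 0.8 * frac,
                      wOnS = 0.05 * u[5], wOffS = 0.05 * (1 - u[5]),
                      tauT = 0.04 + 0.08 * u[3], tauS = 0.4 + 0.4 * u[4],
                      adapt = 0.5 * u[6]),
      "Fast On" = list(wOnT = 0.8 + 0.7 * u[1], wOffT = 0.05 * u[5],
                       tauT = 0.02 + 0.04 * u[3],
                       wOnS = 0.4 * frac, wOffS = 0,
                       tauS = 0.15 + 0.25 * u[4], adapt = 0.8 * u[6]),
      "Slow On" = list(wOnT = 0.15 * u[5] + 0.5 * frac, wOffT = 0,
                       wOnS = 0.6 + 0.8 * u[1], wOffS = 0,
                       tauT = 0.15 + 0.15 * u[3], tauS = 0.4 + 1.6 * frac,
                       adapt = 0.25 * u[6]),
      "Uncertain" = list(wOnT = 0.1 + 0.5 * frac, wOffT = 0.4 - 0.3 * frac,
                         wOnS = 0.25 * u[3], wOffS = 0.25 * u[4],
                         tauT = 0.05 + 0.2 * u[5], tauS = 0.5 + 1.5 * u[6],
                         adapt = 0.3))
    p$f0 <- f0; p$bw <- bw; p$c0 <- min(c0, 0.5)
    rate <- chirpResponse(p)
    # per-type multiplicative fingerprint: smooth seeded gain modulation,
    # individualizing the waveform without changing response polarity
    fp <- lp(rnorm(length(rate)), 0.4, fsS)
    rate <- rate * exp(1.2 * fp / max(stats::sd(fp), 1e-12))
    ct <- resample(toCalcium(rate, fsS), fsS, sampleRate, nChirp)
    ct <- ct / max(abs(ct))

    polarity <- switch(sg, "Off" = -1, "On-Off" = 0,
                       "Fast On" = 1, "Slow On" = 1,
                       "Uncertain" = sample(c(-1, 1), 1))
    bp <- list(
      wOn = switch(sg, "Off" = 0.1, "On-Off" = 1, "Fast On" = 1,
                   "Slow On" = 1, "Uncertain" = 0.6),
      wOff = switch(sg, "Off" = 1, "On-Off" = 0.9, "Fast On" = 0.1,
                    "Slow On" = 0.15, "Uncertain" = 0.4),
      bumpW = 0.10 + 0.08 * u[2])
    bt <- resample(toCalcium(barResponse(bp), fsS), fsS, sampleRate, nBar)
    bt <- bt / max(abs(bt))

    templates[[g]] <- list(
      group_id = g,
      name = sprintf("G%d", g),
      super_group = sg,
      chirp_template = ct,
      bar_template = bt,
      ds_flag = g %in% dsGroups,
      os_flag = g %in% osGroups,
      preferred_angle = (g * 45) %% 360,
      tuning_kappa = if (g %in% c(dsGroups, osGroups)) 1.5 + u[5] else 0.08,
      rf_sigma_um = c(20 + 14 * u[3], 20 + 14 * u[4]),
      rf_polarity = polarity,
      peak_lag_s = 0.08 + 0.12 * u[6],
      soma_mean = if (g %in% alphaGroups) 170 else 70 + 50 * u[1],
      soma_sdlog = 0.18,
      is_alpha_like = g %in% alphaGroups)
  }

  # baseline abundances: free parameters of the simulation; a handful of
  # dominant types per super-group plus a heavy "Uncertain" tail, as in
  # typical GCL survey data
  w <- 0.4 + runif(32)
  w[32] <- 3; w[17] <- 2; w[31] <- 1.8; w[27] <- 1.5; w[11] <- 1.3
  ab <- w / sum(w)
  names(ab) <- sprintf("G%d", 1:32)
  for (g in 1:32) templates[[g]]$baseline_abundance <- ab[[g]]

  new("TypeLibrary", templates = templates, abundance = ab,
      sampleRate = sampleRate, seed = as.integer(seed))
}

#' Default degeneration schedules
#'
#' Returns the responsiveness multipliers and RF perturbations for a
#' genotype. The wild-type schedule is identically 1. The rd10 default
#' encodes the qualitative progression of photoreceptor loss: Off-pathway
#' types decline first (already reduced at P30), On-Off next, Slow On from
#' P45, Fast On mainly from P90, and Uncertain last, with responsiveness
#' near zero for all super-groups by P180. rd10 receptive fields are made
#' slightly smaller at P30/P45 (scale 0.95) and faster at P45 (kinetics
#' scale 0.85). The exact numbers are simulation configuration, not claims
#' about the biology.
#'
#' @param genotype "wt" or "rd10"
#' @return a [DegenerationSchedule-class]
#' @examples
#' degenerationSchedule("rd10")
#' @export
degenerationSchedule <- function(genotype = c("wt", "rd10")) {
  genotype <- match.arg(genotype)
  dn <- list(SUPER_GROUPS, AGES)
  ones <- matrix(1, 5, 4, dimnames = dn)
  if (genotype == "wt") {
    return(new("DegenerationSchedule", multipliers = ones,
               rfSizeScale = ones, kineticsScale = ones, noiseScale = ones))
  }
  mult <- matrix(c(
    # P30  P45   P90   P180
    0.45, 0.20, 0.06, 0.010,   # Off
    0.70, 0.40, 0.12, 0.010,   # On-Off
    1.00, 0.80, 0.35, 0.020,   # Fast On
    0.90, 0.55, 0.22, 0.020,   # Slow On
    1.00, 1.00, 0.90, 0.030),  # Uncertain
    nrow = 5, byrow = TRUE, dimnames = dn)
  rfs <- ones; rfs[, c("P30", "P45")] <- 0.95
  kin <- ones; kin[, "P45"] <- 0.85
  new("DegenerationSchedule", multipliers = mult,
      rfSizeScale = rfs, kineticsScale = kin, noiseScale = ones)
}
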