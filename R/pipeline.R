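## End-to-end analysis pipeline: preprocessing, quality gating, tuning,
## classification and cohort statistics for one or more cohorts.

#' Analyze a cohort end-to-end
#'
#' Runs the full chirp/bar analysis for every cell: detrending, baseline
#' normalization, snippeting, quality indexing and the responsiveness gate;
#' then, for responsive cells, SVD tuning with DSI/OSI and the permutation
#' test, feature extraction, nearest-template classification with the
#' confidence-score gate, the On-Off index and the alpha-RGC flag.
#'
#' @param cohort an [RGCCohort-class] with chirp and bar traces.
#' @param basis classifier feature basis from [featureBasis()]; must be
#'   built from the same library across cohorts that are compared.
#' @param nPerm permutations for the DS/OS tests.
#' @param seed integer seed for the permutation tests.
#' @return list with:
#'   \describe{
#'     \item{cells}{data.frame, one row per cell: quality indices,
#'       responsiveness, dsi/osi and p-values, group assignment,
#'       confidence, inclusion, OOi and bin, alpha flag, plus the
#'       simulation ground truth when present}
#'     \item{pre}{the [preprocessCohort()] result}
#'     \item{chirpMeans}{T x nCell matrix of trial-mean chirp snippets}
#'   }
#' @export
analyzeCohort <- function(cohort, basis, nPerm = 300L, seed = 1L) {
  pre <- preprocessCohort(cohort)
  cd <- as.data.frame(cellData(cohort)[
    , setdiff(colnames(cellData(cohort)), "gt_rf")])
  n <- nCells(cohort)
  cells <- cbind(cd[, setdiff(names(cd), "cell_id")],
                 pre$qi[, c("qi_chirp", "qi_mb", "responsive")])
  cells <- cbind(cell_id = pre$qi$cell_id, cells)
  cells$dsi <- NA_real_; cells$osi <- NA_real_
  cells$p_ds <- NA_real_; cells$p_os <- NA_real_
  cells$group_id <- NA_integer_; cells$confidence <- NA_real_
  cells$included <- FALSE; cells$super_group <- NA_character_
  cells$ooi <- NA_real_; cells$ooi_bin <- NA_character_
  cells$is_alpha <- alphaFlag(cells$soma_size)

  mb <- cohort@stimuli$bar
  trialDirs <- mb@directions[as.vector(t(mb@trialOrder))]
  chirpSn <- pre$snippets$chirp
  barSn <- pre$snippets$bar
  chirpMeans <- matrix(NA_real_, dim(chirpSn)[1], n)

  for (i in seq_len(n)) {
    if (!cells$responsive[i]) next
    okChirp <- !anyNA(chirpSn[, , i])
    okBar <- !anyNA(barSn[, , i])
    if (okChirp) chirpMeans[, i] <- rowMeans(chirpSn[, , i])
    if (okBar) {
      ta <- tuningAnalysis(barSn[, , i], trialDirs,
                           directions = mb@directions,
                           nPerm = nPerm, seed = seed + i)
      cells$dsi[i] <- ta$dsi; cells$osi[i] <- ta$osi
      cells$p_ds[i] <- ta$p_ds; cells$p_os[i] <- ta$p_os
    }
    if (okChirp && okBar) {
      barMean <- rowMeans(barSn[, , i])
      fv <- extractFeatures(chirpMeans[, i], barMean, cells$p_ds[i],
                            cells$soma_size[i], basis)
      asg <- assignType(fv, basis)
      cells$group_id[i] <- asg$group_id
      cells$confidence[i] <- asg$confidence
      cells$included[i] <- asg$included
      cells$super_group[i] <- asg$super_group
    }
    if (okChirp) {
      amp <- onOffAmplitudes(chirpMeans[, i], cohort@sampleRate)
      oo <- onOffIndex(amp$a_on, amp$a_off)
      cells$ooi[i] <- oo$ooi; cells$ooi_bin[i] <- oo$bin
    }
  }
  list(cells = cells, pre = pre, chirpMeans = chirpMeans)
}

#' Simulate and analyze a full study
#'
#' Simulates wild-type and rd10 cohorts over the requested ages with the
#' default degeneration schedules, runs [analyzeCohort()] on each, and
#' aggregates the cohort statistics: per-field responsive fractions, the
#' per-age abundance table with binomial tests, super-group relative
#' abundances and the resilience ranking.
#'
#' @param seed integer master seed.
#' @param nFields fields per (genotype, age) cohort.
#' @param ages ages to simulate.
#' @param genotypes genotypes to simulate.
#' @param nPerm permutations for the DS/OS tests.
#' @param library optional [TypeLibrary-class] (default from `seed`).
#' @return list with `cells` (combined per-cell table), `responsive`
#'   (per-cohort summaries), `table` (abundance table), `supergroups`,
#'   `ranking`, `library`
#' @export
runStudy <- function(seed = 1L, nFields = 3L, ages = AGES,
                     genotypes = c("wt", "rd10"), nPerm = 200L,
                     library = NULL) {
  if (is.null(library)) library <- makeTypeLibrary(seed = seed)
  basis <- featureBasis(library)
  allCells <- list(); respo <- list()
  k <- 0L
  for (gt in genotypes) for (ag in ages) {
    k <- k + 1L
    coh <- simulateCohort(gt, ag, library = library, nFields = nFields,
                          seed = seed + 1000L * k,
                          stimuli = c("chirp", "bar"))
    an <- analyzeCohort(coh, basis, nPerm = nPerm, seed = seed + k)
    allCells[[k]] <- an$cells
    rf <- responsiveFraction(an$cells$field_id, an$cells$responsive)
    respo[[k]] <- data.frame(genotype = gt, age = ag,
                             mean_fraction = rf$mean, sd_fraction = rf$sd,
                             n_cells = nrow(an$cells),
                             n_responsive = sum(an$cells$responsive),
                             stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, allCells)
  tab <- cohortTable(cells)
  sg <- supergroupAbundance(tab)
  pooled <- supergroupPooledAbundance(cells)
  list(cells = cells, responsive = do.call(rbind, respo), table = tab,
       supergroups = sg, pooled = pooled,
       ranking = resilienceRanking(pooled),
       library = library)
}
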