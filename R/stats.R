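## Cohort-level statistics: responsiveness, relative type abundance with
## exact binomial testing, group comparisons with rank-biserial effect
## sizes, distribution divergence, correlation matrices, and the headline
## percent-difference summaries.

#' Per-field responsive fractions
#'
#' Fraction of responsive cells per recording field plus the cohort summary
#' (mean and SD across fields). Empty fields are excluded with a warning.
#'
#' @param fieldId field identifier per cell.
#' @param responsive logical per cell.
#' @return list with `perField` (data.frame: field_id, n, n_responsive,
#'   fraction) and `mean`, `sd`
#' @export
responsiveFraction <- function(fieldId, responsive) {
  stopifnot(length(fieldId) == length(responsive))
  keep <- !is.na(fieldId)
  if (!any(keep)) stop("at least one field is required")
  tab <- tapply(responsive[keep], fieldId[keep], function(x) {
    c(n = length(x), k = sum(x))
  })
  pf <- data.frame(field_id = names(tab),
                   n = vapply(tab, `[[`, numeric(1), "n"),
                   n_responsive = vapply(tab, `[[`, numeric(1), "k"),
                   stringsAsFactors = FALSE, row.names = NULL)
  empty <- pf$n == 0
  if (any(empty)) {
    warning(sum(empty), " empty field(s) excluded")
    pf <- pf[!empty, ]
  }
  pf$fraction <- pf$n_responsive / pf$n
  list(perField = pf, mean = mean(pf$fraction), sd = stats::sd(pf$fraction))
}

#' Relative type abundance
#'
#' log2 of the ratio of a type's fraction in the degenerating line over
#' wild-type. Positive values indicate higher abundance in rd10 (resilient),
#' negative values higher abundance in wild-type (vulnerable). If either
#' fraction is zero the value is missing (NA).
#'
#' @param fRd10,fWt type fractions in (0, 1\].
#' @return log2(fRd10 / fWt), NA when either fraction is 0
#' @examples
#' relativeAbundance(0.01, 0.04)  # -2
#' @export
relativeAbundance <- function(fRd10, fWt) {
  ifelse(fRd10 > 0 & fWt > 0, log2(fRd10 / fWt), NA_real_)
}

#' Two-tailed exact binomial abundance test
#'
#' Tests whether the count of a type in the rd10 cohort (k out of n typed
#' cells) is compatible with the wild-type proportion p. Two-tailed with
#' the minimum-likelihood convention: the p-value sums P(X = j) over all
#' outcomes no more likely than the observed one.
#'
#' @param k observed count in rd10 (0 <= k <= n).
#' @param n total typed rd10 cells.
#' @param p expected (wild-type) proportion, in (0, 1).
#' @return two-tailed p-value; NA if p is degenerate
#' @examples
#' binomialAbundanceTest(3, 10, 0.5)  # 0.34375
#' @export
binomialAbundanceTest <- function(k, n, p) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p <= 0 || p >= 1) return(NA_real_)
  stats::binom.test(k, n, p, alternative = "two.sided")$p.value
}

#' Mann-Whitney U comparison with rank-biserial effect size
#'
#' Two-sided Mann-Whitney U test (exact for small tie-free samples, tie-
#' corrected normal approximation otherwise), with U reported for the first
#' sample and the rank-biserial correlation rb = 1 - 2U / (n1 n2). rb is 1
#' when every x ranks below every y, -1 in the opposite case and 0 at
#' U = n1 n2 / 2.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `U`, `p`, `rb`, `n1`, `n2`
#' @examples
#' mwuWithEffect(c(1, 2), c(3, 4))  # U = 0, rb = 1, p = 1/3
#' @export
mwuWithEffect <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  exact <- n1 < 20 && n2 < 20 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, p = wt$p.value, rb = 1 - 2 * U / (n1 * n2), n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, name-stable wrapper
#' around [stats::p.adjust()] so the multiple-testing convention is a
#' single explicit choice.
#'
#' @param p p-values in \[0, 1\] (NA passed through).
#' @return adjusted p-values
#' @export
bhAdjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Jensen-Shannon divergence
#'
#' Base-2 JSD between two histograms on a common binning:
#' JSD = KL(p || m)/2 + KL(q || m)/2 with m the average distribution.
#' Inputs are renormalized; zero bins are handled by the mixture
#' construction (0 log 0 = 0). Ranges from 0 (identical) to 1 (disjoint
#' supports). A zero-mass input is undefined (NA).
#'
#' @param p,q nonnegative histogram vectors of equal length.
#' @return JSD in \[0, 1\], or NA
#' @examples
#' jsd(c(1, 0), c(0, 1))  # 1
#' @export
jsd <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("histograms must be nonnegative")
  if (sum(p) == 0 || sum(q) == 0) return(NA_real_)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Per-type QI-distribution divergence between genotypes
#'
#' Histograms the quality indices of each functional group (20 equal bins
#' on \[0, 1\]) separately for the two genotypes and returns the base-2
#' Jensen-Shannon divergence per group - the signal-to-noise comparison
#' across degeneration. Groups with fewer than `minCells` cells in either
#' genotype are reported as NA ("empty").
#'
#' @param cells per-cell table with genotype, group_id, included and a QI
#'   column.
#' @param qiColumn which QI to compare ("qi_chirp" or "qi_mb").
#' @param nBins histogram bins on \[0, 1\].
#' @param minCells minimum cells per genotype and group.
#' @return data.frame with group_id, jsd, n_wt, n_rd10
#' @export
jsdQIByType <- function(cells, qiColumn = "qi_chirp", nBins = 20L,
                        minCells = 5L) {
  breaks <- seq(0, 1, length.out = nBins + 1L)
  sub <- cells[cells$included %in% TRUE & !is.na(cells$group_id) &
                 !is.na(cells[[qiColumn]]), ]
  out <- data.frame(group_id = 1:32, jsd = NA_real_,
                    n_wt = 0L, n_rd10 = 0L)
  for (g in 1:32) {
    qw <- sub[[qiColumn]][sub$group_id == g & sub$genotype == "wt"]
    qr <- sub[[qiColumn]][sub$group_id == g & sub$genotype == "rd10"]
    out$n_wt[g] <- length(qw); out$n_rd10[g] <- length(qr)
    if (length(qw) < minCells || length(qr) < minCells) next
    hw <- tabulate(findInterval(qw, breaks, rightmost.closed = TRUE), nBins)
    hr <- tabulate(findInterval(qr, breaks, rightmost.closed = TRUE), nBins)
    out$jsd[g] <- jsd(hw, hr)
  }
  out
}

#' Cross-genotype type correlation matrix
#'
#' Pearson correlation between the per-type mean response traces of two
#' cohorts, for every pair of types. The diagonal measures how well each
#' type's response is preserved. Missing or constant traces give NA.
#'
#' @param meanWt,meanRd T x 32 matrices of per-type mean traces
#'   (NA columns = missing types).
#' @return 32 x 32 correlation matrix (rows: wild-type types)
#' @export
typeCorrelationMatrix <- function(meanWt, meanRd) {
  stopifnot(nrow(meanWt) == nrow(meanRd))
  out <- matrix(NA_real_, ncol(meanWt), ncol(meanRd),
                dimnames = list(colnames(meanWt), colnames(meanRd)))
  for (i in seq_len(ncol(meanWt))) {
    a <- meanWt[, i]
    if (anyNA(a) || stats::sd(a) == 0) next
    for (j in seq_len(ncol(meanRd))) {
      b <- meanRd[, j]
      if (anyNA(b) || stats::sd(b) == 0) next
      out[i, j] <- stats::cor(a, b)
    }
  }
  out
}

#' Headline percent difference
#'
#' 100 (mean_wt - mean_rd10) / mean_wt, rounded half-up to one decimal.
#' Positive values mean reduced (or faster, for latencies) in rd10 relative
#' to the wild-type baseline.
#'
#' @param meanWt wild-type group mean (non-zero).
#' @param meanRd10 rd10 group mean.
#' @return signed percentage, one decimal
#' @examples
#' percentDifference(126.9, 120.2)  # 5.3
#' @export
percentDifference <- function(meanWt, meanRd10) {
  if (meanWt == 0) stop("wild-type baseline mean must be non-zero")
  x <- 100 * (meanWt - meanRd10) / meanWt
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Per-age cohort abundance table
#'
#' Builds the per-(age, type) abundance comparison between genotypes from a
#' per-cell table: counts and fractions among CS-included RGCs, the log2
#' relative abundance, the exact binomial test against the wild-type
#' proportion (BH-adjusted per age, significant at adjusted p < 0.01), and
#' missing-type flags.
#'
#' @param cells data.frame with columns genotype ("wt"/"rd10"), age,
#'   group_id, included (logical).
#' @param ages ages to tabulate.
#' @return data.frame with one row per (age, group)
#' @export
cohortTable <- function(cells, ages = intersect(AGES, unique(cells$age))) {
  res <- list()
  for (ag in ages) {
    sub <- cells[cells$age == ag & cells$included %in% TRUE &
                   !is.na(cells$group_id), ]
    nWt <- sum(sub$genotype == "wt"); nRd <- sum(sub$genotype == "rd10")
    kWt <- tabulate(sub$group_id[sub$genotype == "wt"], 32L)
    kRd <- tabulate(sub$group_id[sub$genotype == "rd10"], 32L)
    fWt <- if (nWt > 0) kWt / nWt else rep(NA_real_, 32)
    fRd <- if (nRd > 0) kRd / nRd else rep(NA_real_, 32)
    pv <- vapply(1:32, function(g) {
      if (nRd == 0 || is.na(fWt[g]) || fWt[g] <= 0 || fWt[g] >= 1)
        return(NA_real_)
      binomialAbundanceTest(kRd[g], nRd, fWt[g])
    }, numeric(1))
    padj <- bhAdjust(pv)
    res[[ag]] <- data.frame(
      age = ag, group_id = 1:32, super_group = superGroup(1:32),
      n_wt = kWt, n_rd10 = kRd, f_wt = fWt, f_rd10 = fRd,
      relative_abundance = relativeAbundance(fRd, fWt),
      p_binomial = pv, p_adjusted = padj,
      significant = !is.na(padj) & padj < 0.01,
      missing = kWt == 0 | kRd == 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Super-group relative abundance summary
#'
#' Mean (and SD) of the per-type log2 relative abundances within each
#' functional super-group and age; missing types are excluded.
#'
#' @param tab output of [cohortTable()].
#' @return data.frame with age, super_group, mean_log2, sd_log2, n_types
#' @export
supergroupAbundance <- function(tab) {
  sp <- split(tab, list(tab$age, tab$super_group), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d$relative_abundance[!is.na(d$relative_abundance)]
    data.frame(age = d$age[1], super_group = d$super_group[1],
               mean_log2 = if (length(v)) mean(v) else NA_real_,
               sd_log2 = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_types = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled super-group relative abundance
#'
#' log2 relative abundance computed directly from the pooled cell counts of
#' each functional super-group (fractions among CS-included cells), per age.
#' Compared with averaging the per-type log2 values, pooling weights types
#' by their cell counts and is unaffected by misassignments between types
#' of the same super-group, so it is the preferred estimator at the
#' super-group level.
#'
#' @param cells per-cell table with genotype, age, super_group, included.
#' @param ages ages to tabulate.
#' @return data.frame with age, super_group, log2_pooled, n_wt, n_rd10
#' @export
supergroupPooledAbundance <- function(cells,
                                      ages = intersect(AGES,
                                                       unique(cells$age))) {
  res <- list()
  for (ag in ages) {
    sub <- cells[cells$age == ag & cells$included %in% TRUE &
                   !is.na(cells$super_group), ]
    nWt <- sum(sub$genotype == "wt"); nRd <- sum(sub$genotype == "rd10")
    kWt <- table(factor(sub$super_group[sub$genotype == "wt"],
                        levels = SUPER_GROUPS))
    kRd <- table(factor(sub$super_group[sub$genotype == "rd10"],
                        levels = SUPER_GROUPS))
    fWt <- if (nWt > 0) as.numeric(kWt) / nWt else rep(NA_real_, 5)
    fRd <- if (nRd > 0) as.numeric(kRd) / nRd else rep(NA_real_, 5)
    res[[ag]] <- data.frame(age = ag, super_group = SUPER_GROUPS,
                            log2_pooled = relativeAbundance(fRd, fWt),
                            n_wt = as.numeric(kWt), n_rd10 = as.numeric(kRd),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Super-group resilience ranking
#'
#' Orders the five functional super-groups by their mean pooled log2
#' relative abundance across the given ages, most resilient (least
#' negative) first.
#'
#' @param pooled output of [supergroupPooledAbundance()].
#' @param ages ages to average over (the late-degeneration P180 cohort is
#'   excluded by default because almost no rd10 cells remain responsive).
#' @return character vector of super-group labels, resilient to vulnerable
#' @export
resilienceRanking <- function(pooled, ages = c("P30", "P45", "P90")) {
  d <- pooled[pooled$age %in% ages & !is.na(pooled$log2_pooled), ]
  m <- tapply(d$log2_pooled, d$super_group, mean)
  names(sort(m, decreasing = TRUE))
}
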