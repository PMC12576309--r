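## Functional type assignment. The published random-forest classifier was
## trained on an external reference dataset; this module provides a
## self-contained, behaviorally analogous surrogate: nearest-template
## matching on a frozen feature basis with a softmax-margin confidence
## score, calibrated only on the synthetic template library.

#' Frozen feature basis for classification
#'
#' Builds the fixed low-dimensional projection used by the classifier:
#' principal directions of the library's chirp templates (20 components)
#' and bar templates (8 components), plus the per-dimension statistics of
#' the template feature matrix used to standardize features. Frozen with the
#' library, so features are reproducible.
#'
#' @param library a [TypeLibrary-class]
#' @param nChirp,nBar number of chirp/bar components.
#' @return list with the projection matrices, centers, template features
#'   and standardization statistics
#' @export
featureBasis <- function(library, nChirp = 20L, nBar = 8L) {
  tp <- library@templates
  Mc <- t(vapply(tp, function(t) t$chirp_template,
                 numeric(length(tp[[1]]$chirp_template))))
  Mb <- t(vapply(tp, function(t) t$bar_template,
                 numeric(length(tp[[1]]$bar_template))))
  pcs <- function(M, k) {
    ctr <- colMeans(M)
    sv <- svd(sweep(M, 2, ctr), nu = 0, nv = k)
    list(center = ctr, rotation = sv$v)
  }
  pc <- pcs(Mc, nChirp); pb <- pcs(Mb, nBar)
  # template feature vectors: projections + DS p-value proxy + soma size
  proj <- function(x, p) as.numeric(crossprod(p$rotation, x - p$center))
  tf <- t(vapply(tp, function(t) {
    c(proj(t$chirp_template, pc), proj(t$bar_template, pb),
      ds = as.numeric(t$ds_flag), soma = t$soma_mean)
  }, numeric(nChirp + nBar + 2L)))
  mu <- colMeans(tf)
  sdv <- apply(tf, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  # template traces as represented by the frozen basis (for trace-space
  # similarity in assignType)
  recon <- function(scores, p) t(p$rotation %*% t(scores) + p$center)
  list(chirp = pc, bar = pb, nChirp = nChirp, nBar = nBar,
       templateFeatures = tf, center = mu, scale = sdv,
       templateChirpRecon = recon(tf[, seq_len(nChirp), drop = FALSE], pc),
       templateBarRecon = recon(tf[, nChirp + seq_len(nBar), drop = FALSE],
                                pb),
       groups = vapply(tp, function(t) t$group_id, integer(1)))
}

#' Extract classification features for one cell
#'
#' Projects the trial-mean chirp and bar snippets onto the frozen feature
#' basis and appends the direction-selectivity evidence (permutation-test
#' p-value, encoded as the indicator p < 0.05) and the soma size. A missing
#' stimulus yields NA features and excludes the cell from typing.
#'
#' @param chirpMean trial-mean normalized chirp snippet (or NULL).
#' @param barMean trial-mean normalized bar snippet (or NULL).
#' @param pDs permutation p-value for direction selectivity.
#' @param somaSize soma size in um^2.
#' @param basis result of [featureBasis()].
#' @return numeric feature vector (constant length) with NA if incomplete
#' @export
extractFeatures <- function(chirpMean, barMean, pDs, somaSize, basis) {
  n <- basis$nChirp + basis$nBar + 2L
  if (is.null(chirpMean) || is.null(barMean) ||
      anyNA(chirpMean) || anyNA(barMean))
    return(rep(NA_real_, n))
  # bring snippets onto the template amplitude scale (peak = 1) so the
  # frozen projection sees comparable inputs
  if (max(abs(chirpMean)) > 0) chirpMean <- chirpMean / max(abs(chirpMean))
  if (max(abs(barMean)) > 0) barMean <- barMean / max(abs(barMean))
  proj <- function(x, p) as.numeric(crossprod(p$rotation, x - p$center))
  c(proj(chirpMean, basis$chirp), proj(barMean, basis$bar),
    as.numeric(!is.na(pDs) && pDs < 0.05), somaSize)
}

#' Reconstruct a chirp template from its features
#'
#' Inverse of the chirp-feature projection; used to verify that the frozen
#' basis retains the template structure.
#'
#' @param features feature vector from [extractFeatures()].
#' @param basis result of [featureBasis()].
#' @return reconstructed chirp time course
#' @export
reconstructChirp <- function(features, basis) {
  sc <- features[seq_len(basis$nChirp)]
  as.numeric(basis$chirp$rotation %*% sc) + basis$chirp$center
}

#' Assign a functional type by nearest template
#'
#' Computes a weighted correlation-based similarity between the cell's
#' features and every template: Pearson correlation of the chirp feature
#' block, of the bar feature block, agreement of the direction-selectivity
#' indicator, and a Gaussian soma-size proximity. The cell is assigned the
#' best-matching group, and the similarity margin between the best and
#' second-best template is converted into a confidence score
#' CS = 1 - exp(-margin / tau) in \[0, 1\]. Cells with CS >= 0.25 are
#' included in type-resolved analyses.
#'
#' @param features feature vector from [extractFeatures()].
#' @param basis result of [featureBasis()].
#' @param tau margin scale of the confidence score.
#' @param weights named weights of the chirp, bar, ds and soma similarity
#'   terms (rescaled to sum to 1).
#' @param somaSd soma-proximity scale, um^2.
#' @return list with `group_id` (NA if unassignable), `confidence`,
#'   `included`, `super_group`, `similarity` (per template)
#' @export
assignType <- function(features, basis, tau = 0.05,
                       weights = c(chirp = 0.65, bar = 0.2, ds = 0.05,
                                   soma = 0.1),
                       somaSd = 40) {
  unassigned <- list(group_id = NA_integer_, confidence = 0,
                     included = FALSE, super_group = NA_character_,
                     similarity = rep(NA_real_, nrow(basis$templateFeatures)))
  if (anyNA(features)) return(unassigned)
  w <- weights / sum(weights)
  ic <- seq_len(basis$nChirp)
  ib <- basis$nChirp + seq_len(basis$nBar)
  ids <- basis$nChirp + basis$nBar + 1L
  iso <- ids + 1L
  if (stats::sd(features[ic]) < 1e-12) return(unassigned)
  tf <- basis$templateFeatures
  blockCor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
    stats::cor(a, b)
  }
  # compare in the trace space represented by the frozen basis: the
  # reconstruction discards components outside the template span (noise)
  recChirp <- as.numeric(basis$chirp$rotation %*% features[ic]) +
    basis$chirp$center
  recBar <- as.numeric(basis$bar$rotation %*% features[ib]) +
    basis$bar$center
  sim <- vapply(seq_len(nrow(tf)), function(g) {
    w[["chirp"]] * blockCor(recChirp, basis$templateChirpRecon[g, ]) +
      w[["bar"]] * blockCor(recBar, basis$templateBarRecon[g, ]) +
      w[["ds"]] * (1 - abs(features[ids] - tf[g, ids])) +
      w[["soma"]] * exp(-(features[iso] - tf[g, iso])^2 / (2 * somaSd^2))
  }, numeric(1))
  if (all(!is.finite(sim))) return(unassigned)
  ord <- order(sim, decreasing = TRUE)
  margin <- sim[ord[1]] - sim[ord[2]]
  cs <- 1 - exp(-margin / tau)
  g <- basis$groups[ord[1]]
  list(group_id = g, confidence = cs, included = cs >= 0.25,
       super_group = superGroup(g), similarity = sim)
}

#' On-Off index
#'
#' Signed balance of the On- and Off-phase response amplitudes:
#' OOi = (a_on - a_off) / (a_on + a_off), binned as
#' Off (-1, -0.2\], On-Off (-0.2, 0.2\], On (0.2, 1\].
#'
#' @param aOn,aOff nonnegative phase amplitudes (not both 0).
#' @return list with `ooi` and `bin`; both NA when undefined
#' @examples
#' onOffIndex(1, 0)     # ooi 1, "On"
#' onOffIndex(0.4, 0.6) # ooi -0.2, "Off" (right-inclusive edge)
#' @export
onOffIndex <- function(aOn, aOff) {
  if (aOn < 0 || aOff < 0) stop("amplitudes must be nonnegative")
  if (aOn + aOff == 0)
    return(list(ooi = NA_real_, bin = NA_character_))
  ooi <- (aOn - aOff) / (aOn + aOff)
  bin <- if (ooi <= -0.2) "Off" else if (ooi <= 0.2) "On-Off" else "On"
  list(ooi = ooi, bin = bin)
}

#' On/Off phase amplitudes from a chirp snippet
#'
#' Peak response in windows locked to the chirp's light onset and offset
#' steps, measured relative to the mean level just before each window
#' (local baseline), rectified at zero. The local reference makes the
#' measure robust to the offsets that detrending introduces between
#' segments.
#'
#' @param chirpMean trial-mean normalized chirp snippet.
#' @param sampleRate sampling rate, Hz.
#' @param onWindow,offWindow time windows in s within the snippet.
#' @param refDur local-baseline duration before each window, s.
#' @return list with `a_on`, `a_off`
#' @export
onOffAmplitudes <- function(chirpMean, sampleRate = RECORDING_RATE_HZ,
                            onWindow = c(2, 5), offWindow = c(5, 8),
                            refDur = 1) {
  idx <- function(w) {
    i <- seq(floor(w[1] * sampleRate) + 1L, ceiling(w[2] * sampleRate))
    i[i >= 1 & i <= length(chirpMean)]
  }
  amp <- function(w) {
    ref <- mean(chirpMean[idx(c(max(w[1] - refDur, 0), w[1]))])
    max(0, max(chirpMean[idx(w)]) - ref)
  }
  list(a_on = amp(onWindow), a_off = amp(offWindow))
}

#' Alpha-RGC flag
#'
#' Alpha RGCs are identified by their distinctly large somata:
#' soma size strictly greater than 136 um^2.
#'
#' @param somaSize soma size in um^2 (> 0).
#' @return logical
#' @examples
#' alphaFlag(c(137, 136, 50))
#' @export
alphaFlag <- function(somaSize) {
  if (any(somaSize <= 0)) stop("soma size must be positive")
  somaSize > 136
}

#' Per-type mean responses
#'
#' Trial-mean response traces averaged over the included cells of each
#' functional group; groups without cells are flagged missing (NA columns).
#'
#' @param meanSnippets T x nCell matrix of per-cell trial-mean snippets.
#' @param groupId per-cell group assignment (NA = unassigned).
#' @param included per-cell inclusion flag (CS gate).
#' @return list with `mean` (T x 32 matrix, NA where missing) and
#'   `missing` (logical vector per group)
#' @export
typeMeanResponses <- function(meanSnippets, groupId, included) {
  out <- matrix(NA_real_, nrow(meanSnippets), 32L,
                dimnames = list(NULL, sprintf("G%d", 1:32)))
  for (g in 1:32) {
    sel <- which(!is.na(groupId) & groupId == g & included)
    if (length(sel))
      out[, g] <- rowMeans(meanSnippets[, sel, drop = FALSE])
  }
  list(mean = out, missing = apply(out, 2, function(x) all(is.na(x))))
}
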