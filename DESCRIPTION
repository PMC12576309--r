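Package: rgcdegen
Title: Functional Typing of Retinal Ganglion Cells During Photoreceptor
    Degeneration
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for two-photon calcium imaging of the
    retinal ganglion cell layer, aimed at quantifying how progressive
    photoreceptor degeneration (as in the rd10 mouse model of retinitis
    pigmentosa) affects functional retinal ganglion cell (RGC) types.
    Provides generators for the chirp, moving-bar and shifted dense-noise
    light stimuli; a forward simulator of wild-type and degenerating GCL
    populations with known ground truth; trace preprocessing
    (Savitzky-Golay detrending, baseline normalization, trial
    snippeting) and repeatability-based quality indices; direction- and
    orientation-selectivity indices with a permutation test;
    spatio-temporal receptive-field estimation via a spline-basis
    penalized linear-Gaussian model with SVD decomposition, 2D Gaussian
    fitting and quality gating; a nearest-template functional type
    classifier with confidence scoring; and cohort-level statistics
    (responsiveness fractions, log2 relative type abundance with exact
    binomial testing, Mann-Whitney U with rank-biserial effect sizes,
    Benjamini-Hochberg correction, Jensen-Shannon divergence and
    percent-difference summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    splines,
    signal,
    minpack.lm,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Classification, Regression
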