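# rgcdegen

Functional typing of retinal ganglion cells (RGCs) during photoreceptor
degeneration, from two-photon calcium imaging of the ganglion cell layer.

In retinitis pigmentosa and its mouse models (rd10), rods and then cones
die while the retina's output neurons, the RGCs, survive and stay
light-responsive for months. Whether the ~32 *functional* RGC types lose
their characteristic responses uniformly or differentially is the question
this package's pipeline quantifies. For people working with GCL population
imaging, it provides the full analysis chain:

- **Stimulus generators** — full-field chirp, moving bar (8 directions),
  and shifted dense binary noise (20 x 15 checks of 40 um at 5 Hz,
  frame-jittered on a 10 um grid).
- **Synthetic cohorts** — a forward simulator of wild-type and
  degenerating GCL populations (linear-nonlinear-calcium response model,
  per-type templates, soma sizes, drift and noise) with known ground
  truth, standing in for recordings.
- **Preprocessing** — Savitzky-Golay detrending (60 s, order 3), baseline
  normalization, trial snippeting, and the repeatability quality index
  `QI = Var_t[<C>_r] / <Var_t[C]>_r`; cells are responsive if
  `QI_chirp >= 0.35` or `QI_bar >= 0.6`.
- **Tuning** — SVD tuning curves; `DSI = |sum r_k e^(i theta_k)| / sum r_k`
  (OSI with doubled angles); add-one permutation tests.
- **Receptive fields** — spline-basis penalized linear-Gaussian model on
  the clipped calcium gradient: `F(x,y,tau) = S b` on a (32, 20, 15) grid
  with (10, 12, 9) cubic B-spline coefficients, full-batch Adam, L1
  penalty; SVD split into spatial/temporal components, 2D Gaussian fit,
  2-SD-ellipse size, main-peak-lag kinetics, and the quality gates
  `QI_SVD > 0.5`, `QI_sRF > 0.5`, lag in [0, 0.3] s.
- **Classification** — a self-contained nearest-template surrogate for the
  published random-forest type classifier, with a softmax-margin
  confidence score and the `CS >= 0.25` inclusion gate; On-Off index;
  alpha-RGC flag (soma > 136 um^2).
- **Cohort statistics** — responsive fractions per field, per-type
  abundance with exact two-tailed binomial tests against wild-type
  proportions (BH-corrected, alpha < 0.01), `log2(rd10/WT)` relative
  abundance, Mann-Whitney U with rank-biserial effect size
  `rb = 1 - 2U/(n1 n2)`, Jensen-Shannon divergence, and the headline
  percent-difference summaries.

## Worked example

Simulate two wild-type recording fields, run the chirp/bar analysis, and
look at the per-cell table:

```r
library(rgcdegen)

lib   <- makeTypeLibrary(seed = 1)        # 32 synthetic type templates
basis <- featureBasis(lib)                # frozen classifier basis
coh   <- simulateCohort("wt", "P30", library = lib, nFields = 2, seed = 7)
coh
#> RGCCohort: 218 cells in 2 fields (wt, P30)
#> stimuli: chirp, bar

an <- analyzeCohort(coh, basis, nPerm = 200, seed = 1)
rf <- responsiveFraction(an$cells$field_id, an$cells$responsive)
sprintf("responsive fraction: %.2f +/- %.2f", rf$mean, rf$sd)
#> "responsive fraction: 0.56 +/- 0.03"

resp <- an$cells[an$cells$responsive & !is.na(an$cells$group_id), ]
head(resp[, c("cell_id", "qi_chirp", "qi_mb", "dsi", "p_ds",
              "group_id", "confidence", "super_group")], 3)
#>           cell_id  qi_chirp     qi_mb        dsi      p_ds group_id confidence super_group
#> 1 wt_P30_f01_c001 0.3737999 0.6746506 0.04374441 0.2388060       11  0.9887680      On-Off
#> 2 wt_P30_f01_c002 0.3868179 0.6763866 0.03167344 0.4676617       10  0.9076613      On-Off
#> 3 wt_P30_f01_c003 0.4839087 0.6475771 0.02273852 0.7661692       17  0.9741066     Fast On
```

About 56% of cells pass the responsiveness gate (the simulator's wild-type
target is ~60%), each typed cell carries its quality indices, selectivity
indices with permutation p-values, group assignment with confidence, and
derived flags. A full degeneration study (both genotypes, four ages,
abundance tables and the super-group resilience ranking) is one call:

```r
st <- runStudy(seed = 1, nFields = 8)
st$ranking
#> [1] "Uncertain" "Fast On"   "Slow On"   "On-Off"    "Off"
```

i.e. with the default degeneration schedule the pipeline recovers the
planted resilience ordering: Off-pathway types lose their responses first,
Fast On and the weakly-responding "Uncertain" cells last.

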