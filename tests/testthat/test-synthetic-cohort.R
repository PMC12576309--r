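test_that("the type library satisfies its structural contracts", {
  lib <- fxLibrary()
  expect_equal(sum(lib@abundance), 1, tolerance = 1e-12)
  tps <- templates(lib)
  expect_length(tps, 32)
  expect_true(any(vapply(tps, function(t) t$ds_flag, logical(1))))
  expect_true(any(vapply(tps, function(t) t$os_flag, logical(1))))
  # templates mutually distinguishable
  ch <- t(vapply(tps, function(t) t$chirp_template,
                 numeric(length(tps[[1]]$chirp_template))))
  cc <- cor(t(ch)); diag(cc) <- 0
  expect_lt(max(cc), 0.95)
  # determinism
  lib2 <- makeTypeLibrary(seed = 1)
  expect_equal(templates(lib2)[[13]]$chirp_template,
               tps[[13]]$chirp_template)
})

test_that("Off templates respond at light offset, not onset", {
  lib <- fxLibrary()
  fs <- lib@sampleRate
  onWin <- round(2 * fs):round(4 * fs)     # after the bright step onset
  offWin <- round(5 * fs):round(7 * fs)    # after the step offset
  for (g in 1:9) {
    tp <- templates(lib)[[g]]
    expect_gt(max(tp$chirp_template[offWin]),
              2 * max(tp$chirp_template[onWin]))
  }
})

test_that("a noiseless cell repeats its chirp response perfectly", {
  lib <- fxLibrary()
  tp <- templates(lib)[[22]]
  cell <- simulateCell(tp, chirp = fxChirp(), noiseScale = 0, seed = 3)
  len <- floor(chirpPeriod(fxChirp()) * RECORDING_RATE_HZ)
  # with every noise source at zero the raw repetitions are identical
  C <- snippetize(cell$traces$chirp, cell$triggers$chirp, len)
  expect_equal(qualityIndex(C), 1)
  expect_identical(max(abs(C - C[, 1])), 0)
  # the full preprocessing path keeps near-perfect repeatability (the
  # detrending filter leaks a little response structure near trace edges)
  det <- detrendTrace(cell$traces$chirp)
  bn <- baselineNormalize(det)
  C2 <- snippetize(bn$trace, cell$triggers$chirp, len)
  expect_gt(qualityIndex(C2), 0.75)
})

test_that("a DS template responds far stronger at its preferred direction", {
  lib <- fxLibrary()
  tp <- templates(lib)[[13]]
  expect_true(tp$ds_flag)
  pref <- rgcdegen:::.tuningFactor(tp$preferred_angle, tp)
  null <- rgcdegen:::.tuningFactor(tp$preferred_angle + 180, tp)
  expect_gt(pref / null, 5)
})

test_that("wild-type cohorts hit the target responsive fraction and abundances", {
  lib <- fxLibrary()
  coh <- simulateCohort("wt", "P45", library = lib, nFields = 6, seed = 31,
                        stimuli = "chirp")
  cd <- as.data.frame(cellData(coh)[, 1:8])
  expect_true(all(cd$soma_size > 0))
  expect_gte(nrow(cd) / 6, 100)
  expect_lte(nrow(cd) / 6, 120)
  expect_lt(abs(mean(cd$gt_responsive) - 0.6), 0.05)
  # type draws follow the baseline abundances (chi-squared GOF)
  counts <- tabulate(cd$gt_group, 32)
  gof <- suppressWarnings(chisq.test(counts, p = lib@abundance))
  expect_gt(gof$p.value, 0.01)
})

test_that("degeneration reduces responsiveness monotonically with age", {
  lib <- fxLibrary()
  sch <- degenerationSchedule("rd10")
  expect_true(all(t(apply(sch@multipliers, 1, diff)) <= 0))
  fr <- vapply(AGES, function(ag) {
    coh <- simulateCohort("rd10", ag, library = lib, schedule = sch,
                          nFields = 2, seed = 17, stimuli = "chirp")
    mean(cellData(coh)$gt_responsive)
  }, numeric(1))
  expect_true(all(diff(fr) < 0.05))       # non-increasing within noise
  expect_lt(fr[["P180"]], 0.02)
  # wild-type schedule is identity
  expect_true(all(degenerationSchedule("wt")@multipliers == 1))
})

test_that("cohort simulation is deterministic and validates inputs", {
  lib <- fxLibrary()
  c1 <- simulateCohort("wt", "P30", library = lib, nFields = 1, seed = 9,
                       stimuli = "chirp")
  c2 <- simulateCohort("wt", "P30", library = lib, nFields = 1, seed = 9,
                       stimuli = "chirp")
  expect_identical(traces(c1, "chirp"), traces(c2, "chirp"))
  expect_identical(cellData(c1)$gt_group, cellData(c2)$gt_group)
  expect_error(simulateCohort("wt", "P33", library = lib), "arg")
  # cell ids encode field and index
  expect_match(cellData(c1)$cell_id[1], "^wt_P30_f01_c001$")
})

test_that("cohorts round-trip through the CSV serialization", {
  lib <- fxLibrary()
  coh <- simulateCohort("wt", "P30", library = lib, nFields = 1, seed = 5,
                        stimuli = "chirp", fieldSizeRange = c(8L, 10L))
  dir <- tempfile("cohort")
  writeCohortCSV(coh, dir)
  back <- readCohortCSV(dir)
  expect_equal(traces(back, "chirp"), traces(coh, "chirp"),
               tolerance = 1e-12)
  expect_equal(cellData(back)$cell_id, cellData(coh)$cell_id)
  expect_equal(triggerTimes(back, "chirp"), triggerTimes(coh, "chirp"))
  unlink(dir, recursive = TRUE)
})
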