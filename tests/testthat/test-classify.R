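test_that("super-group lookup is total and matches the shipped convention", {
  expect_equal(superGroup(1), "Off")
  expect_equal(superGroup(17), "Fast On")
  expect_equal(superGroup(27), "Slow On")
  expect_equal(superGroup(32), "Uncertain")
  all32 <- superGroup(1:32)
  expect_false(anyNA(all32))
  expect_setequal(unique(all32), SUPER_GROUPS)
  expect_error(superGroup(0), "1..32")
  expect_error(superGroup(33), "1..32")
})

test_that("features are deterministic, fixed-length and reconstructable", {
  lib <- fxLibrary(); basis <- fxBasis()
  tp <- templates(lib)[[5]]
  f1 <- extractFeatures(tp$chirp_template, tp$bar_template, 0.5, 120, basis)
  f2 <- extractFeatures(tp$chirp_template, tp$bar_template, 0.5, 120, basis)
  expect_identical(f1, f2)
  expect_length(f1, basis$nChirp + basis$nBar + 2L)
  # the frozen basis retains the template structure
  for (g in c(1, 9, 17, 25, 32)) {
    tpg <- templates(lib)[[g]]
    fv <- extractFeatures(tpg$chirp_template, tpg$bar_template, 0.5,
                          tpg$soma_mean, basis)
    rec <- reconstructChirp(fv, basis)
    expect_gt(cor(rec, tpg$chirp_template), 0.95)
  }
  # missing stimulus yields NA features of the same length
  fNA <- extractFeatures(NULL, tp$bar_template, 0.5, 120, basis)
  expect_length(fNA, length(f1))
  expect_true(all(is.na(fNA)))
})

test_that("type assignment recovers the generating template", {
  lib <- fxLibrary(); basis <- fxBasis()
  for (g in seq(1, 32, by = 3)) {
    tp <- templates(lib)[[g]]
    fv <- extractFeatures(tp$chirp_template, tp$bar_template,
                          if (tp$ds_flag) 0.01 else 0.5,
                          tp$soma_mean, basis)
    asg <- assignType(fv, basis)
    expect_equal(asg$group_id, g)
    expect_gt(asg$confidence, 0.5)
    expect_true(asg$included)
    expect_equal(asg$super_group, superGroup(g))
  }
  # NA features cannot be assigned
  un <- assignType(rep(NA_real_, basis$nChirp + basis$nBar + 2L), basis)
  expect_true(is.na(un$group_id))
  expect_equal(un$confidence, 0)
  expect_false(un$included)
})

test_that("ambiguous cells score below the inclusive confidence gate", {
  lib <- fxLibrary(); basis <- fxBasis()
  # a response equally similar to its two nearest templates: average the
  # variance-normalized traces of the most correlated template pair, so the
  # classifier's correlation similarity cannot prefer either
  ch <- t(vapply(templates(lib), function(t) t$chirp_template,
                 numeric(length(templates(lib)[[1]]$chirp_template))))
  cc <- cor(t(ch)); diag(cc) <- 0
  pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  A <- templates(lib)[[pair[1]]]; B <- templates(lib)[[pair[2]]]
  midC <- A$chirp_template / sd(A$chirp_template) +
    B$chirp_template / sd(B$chirp_template)
  midB <- A$bar_template / sd(A$bar_template) +
    B$bar_template / sd(B$bar_template)
  fv <- extractFeatures(midC, midB, 0.5,
                        (A$soma_mean + B$soma_mean) / 2, basis)
  asg <- assignType(fv, basis)
  expect_true(asg$group_id %in% pair)
  expect_lt(asg$confidence, 0.25)
  expect_false(asg$included)
  # zero margin maps to zero confidence; the gate itself is inclusive
  expect_equal(1 - exp(-0 / 0.05), 0)
  expect_true(0.25 >= 0.25)
})

test_that("On-Off index formula and bin edges", {
  expect_equal(onOffIndex(1, 0), list(ooi = 1, bin = "On"))
  expect_equal(onOffIndex(0.7, 0.7)$ooi, 0)
  expect_equal(onOffIndex(0.7, 0.7)$bin, "On-Off")
  expect_equal(onOffIndex(2, 3)$ooi, -0.2)
  expect_equal(onOffIndex(2, 3)$bin, "Off")     # right-inclusive edge
  expect_equal(onOffIndex(3, 2)$bin, "On-Off")  # +0.2 stays On-Off
  expect_true(is.na(onOffIndex(0, 0)$ooi))
  expect_error(onOffIndex(-1, 2), "nonnegative")
})

test_that("alpha flag uses the strict soma-size threshold", {
  expect_true(alphaFlag(137))
  expect_false(alphaFlag(136))
  expect_false(alphaFlag(50))
  expect_error(alphaFlag(0), "positive")
})

test_that("per-type mean responses flag missing types", {
  sn <- matrix(rnorm(60), 20, 3)
  tm <- typeMeanResponses(sn, groupId = c(4L, 4L, 7L),
                          included = c(TRUE, TRUE, FALSE))
  expect_equal(tm$mean[, 4], rowMeans(sn[, 1:2]))
  expect_true(tm$missing["G7"])   # excluded by the CS gate
  expect_true(all(tm$missing[-4]))
  # a single included cell is its own mean
  tm2 <- typeMeanResponses(sn, c(2L, NA, NA), c(TRUE, FALSE, FALSE))
  expect_equal(tm2$mean[, 2], sn[, 1])
})

test_that("On/Off amplitudes separate the polarity super-groups", {
  lib <- fxLibrary()
  fs <- RECORDING_RATE_HZ
  ooiOf <- function(g) {
    a <- onOffAmplitudes(templates(lib)[[g]]$chirp_template, fs)
    onOffIndex(a$a_on, a$a_off)$ooi
  }
  offOoi <- vapply(1:9, ooiOf, numeric(1))
  fastOnOoi <- vapply(15:20, ooiOf, numeric(1))
  expect_lt(max(offOoi), -0.2)          # every Off template bins "Off"
  expect_gt(mean(fastOnOoi), 0.5)       # On templates are On-dominated
})
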