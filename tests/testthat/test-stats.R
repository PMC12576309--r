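# Exact-test oracles are computed in-test by direct enumeration and frozen
# closed forms, independently of the implementation path.

binomTwoTailedOracle <- function(k, n, p) {
  pmf <- dbinom(0:n, n, p)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

test_that("two-tailed binomial test matches the enumeration oracle", {
  expect_equal(binomialAbundanceTest(3, 10, 0.5), 0.34375)
  expect_equal(binomTwoTailedOracle(3, 10, 0.5), 0.34375)
  expect_equal(binomialAbundanceTest(5, 10, 0.5), 1)  # observed at the mode
  expect_lt(binomialAbundanceTest(0, 50, 0.5), 1e-13)
  set.seed(19)
  for (i in 1:25) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(binomialAbundanceTest(k, n, p),
                 binomTwoTailedOracle(k, n, p), tolerance = 1e-12)
  }
  expect_true(is.na(binomialAbundanceTest(3, 10, 0)))
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(c(0.2, 0.8)), c(0.4, 0.8))
  # never decreases, capped at 1; BH rejections cover Bonferroni's
  set.seed(7)
  p <- runif(20)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  bonf <- p.adjust(p, "bonferroni")
  expect_true(all(adj[bonf < 0.05] < 0.05))
})

test_that("Mann-Whitney U with rank-biserial endpoints and exact p", {
  r <- mwuWithEffect(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$rb, 1)
  expect_equal(r$p, 2 / 6)  # enumeration over C(4,2) rank configurations
  # U at half the maximum gives rb = 0
  r2 <- mwuWithEffect(c(1, 4), c(2, 3))
  expect_equal(r2$U, 2)     # n1 n2 / 2
  expect_equal(r2$rb, 0)
  r3 <- mwuWithEffect(c(3, 4), c(1, 2))
  expect_equal(r3$rb, -1)
  expect_error(mwuWithEffect(numeric(0), 1:3), "non-empty")
})

test_that("Jensen-Shannon divergence closed forms and properties", {
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  # hand evaluation of the mixture formula
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)),
               0.5 * log2(1 / 0.75) +
                 0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)),
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(10); q <- runif(10)
    expect_equal(jsd(p, q), jsd(q, p))
    expect_gte(jsd(p, q), 0)
    expect_lte(jsd(p, q), 1)
    expect_equal(jsd(p, 2 * p), 0)  # identical after renormalization
  }
  expect_true(is.na(jsd(c(0, 0), c(1, 1))))
})

test_that("relative abundance is antisymmetric and handles missing types", {
  expect_equal(relativeAbundance(0.04, 0.04), 0)
  expect_equal(relativeAbundance(0.08, 0.04), 1)
  expect_equal(relativeAbundance(0.01, 0.04), -2)
  set.seed(12)
  f1 <- runif(10, 0.01, 0.2); f2 <- runif(10, 0.01, 0.2)
  expect_equal(relativeAbundance(f1, f2), -relativeAbundance(f2, f1))
  expect_true(is.na(relativeAbundance(0, 0.1)))
})

test_that("percent differences reproduce the headline rounding", {
  expect_equal(percentDifference(126.9, 120.2), 5.3)
  expect_equal(percentDifference(0.13, 0.11), 15.4)
  expect_equal(percentDifference(5, 5), 0)
  expect_equal(percentDifference(100, 110), -10)
  expect_error(percentDifference(0, 1), "non-zero")
})

test_that("responsive fractions summarize per field", {
  fid <- rep(c("a", "b"), c(100, 50))
  resp <- c(rep(c(TRUE, FALSE), c(60, 40)), rep(c(TRUE, FALSE), c(10, 40)))
  rf <- responsiveFraction(fid, resp)
  expect_equal(sort(rf$perField$fraction), c(0.2, 0.6))
  expect_equal(rf$mean, 0.4)
})

test_that("cohort table computes fractions among included cells only", {
  cells <- data.frame(
    genotype = rep(c("wt", "rd10"), each = 100),
    age = "P30",
    group_id = rep(c(1L, 17L), 100),
    included = rep(c(TRUE, TRUE, TRUE, FALSE), 50))
  tab <- cohortTable(cells, ages = "P30")
  expect_equal(nrow(tab), 32)
  expect_equal(sum(tab$f_wt, na.rm = TRUE), 1)
  expect_equal(sum(tab$f_rd10, na.rm = TRUE), 1)
  expect_true(all(tab$missing[!tab$group_id %in% c(1, 17)]))
})

test_that("type correlation matrix flags missing and degenerate traces", {
  tm <- matrix(NA_real_, 30, 32, dimnames = list(NULL, sprintf("G%d", 1:32)))
  tm[, 1] <- sin(1:30); tm[, 2] <- cos(1:30)
  tm2 <- tm
  tm2[, 2] <- -cos(1:30)
  cm <- typeCorrelationMatrix(tm, tm2)
  expect_equal(cm[1, 1], 1)
  expect_equal(cm[2, 2], -1)
  expect_true(is.na(cm[3, 3]))
})

test_that("per-type QI divergence flags sparse groups and detects shifts", {
  set.seed(23)
  cells <- data.frame(
    genotype = rep(c("wt", "rd10"), each = 120),
    group_id = rep(1:2, 120),
    included = TRUE,
    qi_chirp = c(runif(120, 0.4, 0.9),                 # wt: high QI
                 ifelse(rep(1:2, 60) == 1,
                        runif(120, 0.0, 0.3),          # rd10 G1: degraded
                        runif(120, 0.4, 0.9))))        # rd10 G2: unchanged
  jt <- jsdQIByType(cells)
  expect_gt(jt$jsd[1], 0.8)            # nearly disjoint distributions
  expect_lt(jt$jsd[2], 0.4)
  expect_true(all(is.na(jt$jsd[3:32])))  # empty groups
})
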