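test_that("detrending reproduces polynomial trends exactly", {
  fs <- RECORDING_RATE_HZ
  n <- 800
  tt <- (seq_len(n) - 1) / fs
  cubic <- 2 + 0.5 * tt - 0.02 * tt^2 + 3e-4 * tt^3
  out <- detrendTrace(cubic, fs, windowS = 60, order = 3)
  # an order-3 filter reproduces cubics exactly away from the (mirrored)
  # edges, where the padded input is no longer a cubic
  interior <- 235:(n - 234)
  expect_lt(max(abs(out[interior])), 1e-8 * max(abs(cubic)))
  expect_equal(detrendTrace(rep(7, n), fs), rep(0, n))
  expect_error(detrendTrace(rnorm(100), fs), "too short")
})

test_that("detrending white noise matches a direct sliding-polynomial oracle", {
  set.seed(11)
  fs <- RECORDING_RATE_HZ
  x <- rnorm(1200)
  win <- 469L  # 60 s at 7.8125 Hz, rounded odd
  out <- detrendTrace(x, fs, windowS = 60, order = 3)
  oracle <- x - slidingPolySmooth(x, win, 3)
  expect_equal(out, oracle, tolerance = 1e-10)
  expect_lt(abs(var(out) / var(oracle) - 1), 0.05)
})

test_that("detrending is approximately idempotent on smooth inputs", {
  fs <- RECORDING_RATE_HZ
  tt <- (seq_len(1600) - 1) / fs
  # a trend the filter reproduces exactly (polynomial family) detrends to
  # the same result no matter how often it is applied; the comparison
  # excludes samples within one window of the (mirror-padded) edges, which
  # the second pass can reach
  x <- 3 - 0.2 * tt + 0.005 * tt^2 + 1e-4 * tt^3
  d1 <- detrendTrace(x, fs)
  d2 <- detrendTrace(d1, fs)
  interior <- 470:(1600 - 469)
  expect_lt(max(abs((d2 - d1)[interior])), 1e-6 * diff(range(x)))
  # for band-limited physiological signals the second pass changes the
  # result by no more than the filter's stop-band leakage (~1%)
  y <- sin(2 * pi * 0.5 * tt)
  e1 <- detrendTrace(y, fs); e2 <- detrendTrace(e1, fs)
  expect_lt(max(abs((e2 - e1)[interior])), 0.01 * diff(range(y)))
})

test_that("baseline normalization arithmetic, flagging and idempotence", {
  x <- c(rep(5, 8), 10, 15)
  bn <- baselineNormalize(x)
  expect_true(bn$ok)
  expect_equal(bn$baseline, 5)
  expect_equal(bn$scale, 10)               # peak 15 - baseline 5
  expect_equal(max(bn$trace), 1)
  expect_equal(mean(bn$trace[1:8]), 0)     # baseline subtraction is exact
  # degenerate inputs flagged, not an exception
  expect_false(baselineNormalize(rep(0, 20))$ok)
  expect_false(baselineNormalize(c(rep(5, 8), 4, 3))$ok)  # max at baseline
  # idempotence on an already-normalized trace
  bn2 <- baselineNormalize(bn$trace)
  expect_equal(bn2$trace, bn$trace)
  expect_error(baselineNormalize(1:5), "at least 8")
})

test_that("snippeting indexes by nearest sample and validates triggers", {
  C <- snippetize(0:99, c(0, 10), snippetLen = 5, sampleRate = 1)
  expect_equal(C, cbind(0:4, 10:14))
  # sub-half-sample misalignment rounds to the same columns
  C2 <- snippetize(0:99, c(0.4, 10.4), snippetLen = 5, sampleRate = 1)
  expect_equal(C2, C)
  expect_error(snippetize(0:99, 10, 5, 1), "at least 2")
  expect_error(snippetize(0:99, c(0, 98), 5, 1), "98")
})

test_that("quality index closed forms and degenerate cases", {
  s <- sin(seq_len(50))
  expect_equal(qualityIndex(cbind(s, s, s)), 1)       # identical repetitions
  expect_equal(qualityIndex(matrix(c(1, 0, 0, 1), 2, 2)), 0)
  expect_equal(qualityIndex(matrix(5, 10, 3)), 0)      # all-constant
  expect_error(qualityIndex(matrix(1, 1, 5)), "T >= 2")
})

test_that("quality index approaches 1/R for independent noise", {
  set.seed(21)
  qis <- replicate(100, qualityIndex(matrix(rnorm(1000 * 4), 1000, 4)))
  expect_lt(abs(mean(qis) - 0.25), 0.05)
})

test_that("quality index is invariant to offset and scale", {
  set.seed(3)
  C <- matrix(rnorm(200), 50, 4) + sin(seq_len(50))
  q0 <- qualityIndex(C)
  expect_equal(qualityIndex(C + 7), q0)
  expect_equal(qualityIndex(C * -3.2), q0)
})

test_that("expected quality index decreases with added noise", {
  set.seed(4)
  s <- sin(seq_len(200) / 5)
  q <- vapply(c(0.1, 0.3, 1, 3), function(sd) {
    mean(replicate(40, qualityIndex(s + matrix(rnorm(200 * 5, 0, sd), 200, 5))))
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("responsiveness gate uses inclusive thresholds on either index", {
  expect_true(gateResponsive(0.35, 0.0))
  expect_false(gateResponsive(0.34, 0.59))
  expect_true(gateResponsive(0.0, 0.60))
  expect_false(gateResponsive(NA, 0.5))
  expect_true(gateResponsive(NA, 0.6))
})
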