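test_that("chirp waveform satisfies its segment and range contracts", {
  ch <- fxChirp()
  fs <- ch@sampleRate
  one <- ch@trace[seq_len(length(ch@trace) / ch@nReps)]
  # initial baseline is constant background
  base <- one[seq_len(round(2 * fs))]
  expect_true(all(base == 0.5))
  expect_gte(min(ch@trace), 0)
  expect_lte(max(ch@trace), 1)
  # repetitions bit-identical
  reps <- matrix(ch@trace, ncol = ch@nReps)
  expect_identical(max(abs(reps - reps[, 1])), 0)
  expect_error(makeChirp(durations = c(baseline = -1, step_on = 3,
    step_off = 3, gap1 = 2, freq_sweep = 8, gap2 = 3, amp_sweep = 8,
    tail = 3)), "positive")
})

test_that("frequency sweep contains the analytic number of cycles", {
  ch <- fxChirp()
  fs <- ch@sampleRate
  one <- ch@trace[seq_len(length(ch@trace) / ch@nReps)]
  segs <- ch@segments
  t0 <- sum(segs$duration[1:4])
  dur <- segs$duration[segs$name == "freq_sweep"]
  seg <- one[round(t0 * fs) + seq_len(round(dur * fs))]
  zc <- sum(diff(sign(seg - 0.5)) != 0)
  # cycles of a linear 0.5 -> 8 Hz sweep over 8 s: mean frequency x duration
  cycles <- (0.5 + 8) / 2 * dur
  expect_lte(abs(zc / 2 - cycles), 1)
})

test_that("moving bar timing, direction set and determinism hold", {
  mb <- makeMovingBar(fieldExtent = 1, speed = 1, barSize = c(0.3, 1),
                      seed = 4)
  expect_equal(mb@sweepDuration, 1.3)  # (1 + 0.3) mm at 1 mm/s
  expect_setequal(mb@directions, seq(0, 315, by = 45))
  # every direction exactly once per repetition
  expect_true(all(apply(mb@trialOrder, 1, function(r) setequal(r, 1:8))))
  mb2 <- makeMovingBar(fieldExtent = 1, speed = 1, barSize = c(0.3, 1),
                       seed = 4)
  expect_identical(mb@trialOrder, mb2@trialOrder)
  expect_error(makeMovingBar(nDirections = 4L), "8 directions")
  expect_error(makeMovingBar(fieldExtent = -1), "positive")
})

test_that("shifted dense noise is balanced, complete and deterministic", {
  sn <- makeShiftedDenseNoise(duration = 30, seed = 9)
  expect_identical(dim(sn@frames)[3], 150L)        # 5 Hz x 30 s
  expect_true(all(sn@frames %in% c(0L, 1L)))
  expect_lt(abs(mean(sn@frames) - 0.5), 0.02)      # pooled balance
  expect_true(all(sn@shiftOffsets %% 10 == 0))
  sn2 <- makeShiftedDenseNoise(duration = 30, seed = 9)
  expect_identical(sn@frames, sn2@frames)
  expect_identical(sn@shiftOffsets, sn2@shiftOffsets)
  expect_error(makeShiftedDenseNoise(duration = 30), "seed")
})

test_that("rasterization is the identity on the native grid at zero shift", {
  sn <- makeShiftedDenseNoise(duration = 2, seed = 2)
  sn@shiftOffsets[] <- 0L
  fr <- rasterizeNoise(sn, targetGrid = c(20L, 15L), pixelSize = 40)
  expect_equal(fr, array(as.numeric(sn@frames), dim = dim(sn@frames)))
})

test_that("a one-check shift translates the rasterized frame by one check", {
  sn <- makeShiftedDenseNoise(duration = 2, seed = 2)
  sn0 <- sn; sn0@shiftOffsets[] <- 0L
  sn1 <- sn
  sn1@shiftOffsets[] <- 0L
  sn1@shiftOffsets[, 1] <- 40L  # exactly one check along x
  f0 <- rasterizeNoise(sn0, targetGrid = c(20L, 15L), pixelSize = 40)
  f1 <- rasterizeNoise(sn1, targetGrid = c(20L, 15L), pixelSize = 40)
  expect_equal(f1[2:20, , ], f0[1:19, , ])
})

test_that("random shifts preserve the balanced-binary pixel statistics", {
  sn <- makeShiftedDenseNoise(duration = 60, seed = 7)  # 300 frames
  fr <- rasterizeNoise(sn)
  pixMean <- apply(fr, c(1, 2), mean)
  # interior pixels (fully covered under every shift)
  expect_lt(max(abs(pixMean[4:29, 3:18] - 0.5)), 0.1)
  expect_lt(abs(mean(pixMean[4:29, 3:18]) - 0.5), 0.02)
})
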