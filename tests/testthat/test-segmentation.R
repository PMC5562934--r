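test_that("select_channel picks the largest peak-to-peak gyroscope channel", {
  n <- 100
  mk <- function(gx, gy, gz) {
    z <- numeric(n)
    imu_recording("S01", "SQ", list(
      acc_x = z, acc_y = z, acc_z = z,
      gyro_x = gx * sin(seq(0, 2 * pi, length.out = n)),
      gyro_y = gy * sin(seq(0, 2 * pi, length.out = n)),
      gyro_z = gz * sin(seq(0, 2 * pi, length.out = n))))
  }
  expect_equal(select_channel(mk(200, 40, 30)), "gyro_x")
  expect_equal(select_channel(mk(10, 80, 30)), "gyro_y")
  # exact tie resolves to the first channel in canonical order
  expect_equal(select_channel(mk(50, 50, 10)), "gyro_x")
  z0 <- mk(0, 0, 0)
  expect_error(select_channel(z0), "degenerate")
})

test_that("synthetic recordings select their template's dominant channel", {
  cfg <- synthetic_config(n_subjects = 1, seed = 17)
  for (ex in c("DL", "SLSL")) {
    rec <- lowpass(generate_recording(cfg, "S01", ex)$recording)
    expect_equal(select_channel(rec), template_dominant_channel(ex), info = ex)
  }
})

test_that("one sine period segments at its closed-form peak and crossings", {
  x <- sin(2 * pi * (0:49) / 50)
  d <- detect_repetitions(x, fs = 50)
  expect_equal(nrow(d), 1L)
  expect_equal(d$peak, 12L)   # argmax
  expect_equal(d$start, 0L)   # initial zero crossing
  expect_equal(d$end, 25L)    # half-period zero crossing
})

test_that("flat and sub-threshold signals yield no epochs", {
  expect_equal(nrow(detect_repetitions(numeric(100), fs = 50)), 0L)
  # single dominant peak: the smaller lobe stays below half the max
  t <- seq(0, 1, length.out = 200)
  x <- sin(pi * t) + 0.2
  x[1:50] <- 0.4 * sin(pi * t[1:50] * 4)
  d <- detect_repetitions(x, fs = 50, segmenter_config(min_peak_separation_s = 0.1))
  expect_true(all(x[d$peak + 1] >= 0.5 * max(abs(x))))
})

test_that("zero-noise synthetic recordings are recovered within 2 samples", {
  cfg <- synthetic_config(n_subjects = 1, reps_per_set = 10, noise_sd = 0, seed = 41)
  for (ex in exercise_labels()) {
    g <- generate_recording(cfg, "S01", ex)
    seg <- segment_recording(lowpass(g$recording),
                             segmenter_config(resample_length = NA))
    expect_equal(nrow(seg$manifest), nrow(g$truth), info = ex)
    expect_lte(max(abs(seg$manifest$start - g$truth$start)), 2)
    expect_lte(max(abs(seg$manifest$end - g$truth$end)), 2)
    expect_lte(max(abs(seg$manifest$peak - g$truth$peak)), 2)
  }
})

test_that("epochs are ordered, disjoint and well-formed on noisy data", {
  for (seed in c(3, 14, 27)) {
    cfg <- synthetic_config(n_subjects = 1, seed = seed)
    for (ex in c("SQ", "TJ")) {
      g <- generate_recording(cfg, "S01", ex)
      man <- segment_recording(lowpass(g$recording))$manifest
      expect_true(all(man$start < man$peak & man$peak < man$end))
      if (nrow(man) > 1) {
        expect_true(all(diff(man$start) > 0))
        expect_true(all(man$start[-1] >= man$end[-nrow(man)]))
      }
    }
  }
})

test_that("resample_epoch maps epochs to exactly L samples", {
  reps <- generated_repetitions(seed = 11, n_subjects = 1, reps_per_set = 3)
  for (r in reps) {
    expect_equal(r$resampled_length, 250L)
    expect_true(all(vapply(r$channels, length, integer(1)) == 250L))
  }
})

test_that("resampling a constant epoch gives a constant of length L", {
  n <- 40
  ch <- lapply(stats::setNames(nm = imu_channels()), function(.) rep(2.5, n))
  ch$gyro_x <- c(0, sin(pi * seq(0, 1, length.out = n - 2)), 0)
  rec <- imu_recording("S01", "SQ", ch)
  r <- resample_epoch(repetition(rec, 0L, 20L, 40L), 250L)
  expect_equal(r$channels$acc_x, rep(2.5, 250))
})

test_that("resampling a linear ramp matches the per-point interpolation oracle", {
  n <- 101; L <- 250
  ch <- lapply(stats::setNames(nm = imu_channels()), function(.) seq(0, 1, length.out = n))
  rec <- imu_recording("S01", "SQ", ch)
  r <- resample_epoch(repetition(rec, 0L, 50L, n), L)
  # independent oracle: value at output point k is k/(L-1)
  oracle <- vapply(0:(L - 1), function(k) k / (L - 1), numeric(1))
  expect_lt(max(abs(r$channels$acc_x - oracle)), 1e-12)
  # endpoints preserved exactly
  expect_identical(r$channels$acc_x[1], 0)
  expect_identical(r$channels$acc_x[L], 1)
})

test_that("resample_epoch is idempotent at the same length", {
  rep0 <- make_toy_repetition(L = 250)
  rep1 <- resample_epoch(rep0, 250L)
  for (ch in names(rep0$channels))
    expect_lt(max(abs(rep1$channels[[ch]] - rep0$channels[[ch]])), 1e-9)
})

test_that("invalid resample lengths are rejected", {
  expect_error(resample_epoch(make_toy_repetition(), 1L), ">= 2")
  expect_error(segmenter_config(resample_length = 1))
  expect_error(segmenter_config(min_peak_height = 0))
})
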