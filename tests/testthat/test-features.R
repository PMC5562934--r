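test_that("hand-computed features of tiny epochs are reproduced", {
  f <- suppressWarnings(compute_features(c(1, 2, 3), wavelet_spec(level = 1)))
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["median"]], 2)
  expect_equal(f[["range"]], 2)
  expect_equal(f[["max"]], 3)
  expect_equal(f[["idx_max"]], 2)  # 0-based
  expect_equal(f[["min"]], 1)
  expect_equal(f[["idx_min"]], 0)
  expect_equal(f[["energy"]], 14)
  expect_equal(f[["variance"]], 1)

  f2 <- suppressWarnings(compute_features(c(3, 4), wavelet_spec(level = 1)))
  expect_equal(f2[["rms"]], sqrt(12.5))
})

test_that("level crossing rate matches a brute-force sign-change counter", {
  x <- c(1, -1, 1, -1)
  expect_equal(level_crossing_rate(x), 1.0)
  brute <- function(x, lev) {
    s <- x - lev
    cnt <- 0L
    for (i in seq_len(length(s) - 1L))
      if (s[i] * s[i + 1] < 0) cnt <- cnt + 1L
    cnt / (length(x) - 1L)
  }
  set.seed(9)
  for (k in 1:20) {
    y <- stats::rnorm(50)
    expect_equal(level_crossing_rate(y), brute(y, mean(y)))
  }
})

test_that("Higuchi dimension is near 1 for a sine and matches a loop oracle", {
  # independently coded Higuchi estimator (plain loops)
  higuchi_oracle <- function(x, k_max = 10) {
    n <- length(x)
    lk <- numeric(k_max)
    for (k in 1:k_max) {
      lm_ <- c()
      for (m in 1:k) {
        idx <- seq(m, n, by = k)
        if (length(idx) < 2) next
        lng <- 0
        for (j in 2:length(idx)) lng <- lng + abs(x[idx[j]] - x[idx[j - 1]])
        lm_ <- c(lm_, lng * (n - 1) / ((length(idx) - 1) * k) / k)
      }
      lk[k] <- mean(lm_)
    }
    fit <- stats::lm(log(lk) ~ log(1:k_max))
    -unname(stats::coef(fit)[2])
  }
  x <- sin(2 * pi * 3 * (0:249) / 250)
  expect_lt(abs(higuchi_fd(x) - 1), 0.1)
  set.seed(12)
  for (k in 1:5) {
    y <- cumsum(stats::rnorm(200))
    expect_equal(higuchi_fd(y), higuchi_oracle(y), tolerance = 1e-10)
  }
  # white noise has a much higher dimension than a smooth curve
  expect_gt(higuchi_fd(stats::rnorm(250)), 1.5)
})

test_that("db4 wavelet variances reproduce frozen PyWavelets oracle values", {
  k <- 0:249
  w1 <- dwt_db4(sin(2 * pi * 3 * k / 250))
  expect_equal(stats::var(w1$approx), 1.11406251682556, tolerance = 1e-8)
  expect_equal(stats::var(unlist(w1$details)), 0.502997806083552, tolerance = 1e-8)
  w2 <- dwt_db4(0.5 * k / 249 + cos(2 * pi * 7 * k / 250))
  expect_equal(stats::var(w2$approx), 1.70071815516488, tolerance = 1e-8)
  expect_equal(stats::var(unlist(w2$details)), 0.524848546634937, tolerance = 1e-8)
  # single-level coefficients, even and odd lengths
  s <- dwt_db4(c(1, 2, -1, 3, 0, 1, 4, -2), wavelet_spec(level = 1))
  expect_equal(s$approx, c(1.49375682, 0.97322522, 1.49851865, 1.69135356),
               tolerance = 1e-7)
  expect_equal(s$details[[1]], c(2.70267554, -0.42765625, -4.10736544, 1.83234615),
               tolerance = 1e-7)
  s7 <- dwt_db4(c(1, 2, -1, 3, 0, 1, 4), wavelet_spec(level = 1))
  expect_equal(s7$approx, c(5.27904143, 2.3554921, 1.69581672, 0.56914469),
               tolerance = 1e-7)
})

test_that("a level-7 decomposition of a 250-sample epoch is valid", {
  w <- dwt_db4(stats::rnorm(250), wavelet_spec(level = 7))
  expect_length(w$details, 7L)
  expect_equal(vapply(w$details, length, integer(1)),
               c(125L, 63L, 32L, 16L, 8L, 4L, 2L))
  expect_length(w$approx, 2L)
})

test_that("constant epochs return 0 kurtosis/skewness with a warning", {
  expect_warning(f <- compute_features(rep(2, 250)), "constant epoch")
  expect_equal(f[["kurtosis"]], 0)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["sd"]], 0)
})

test_that("derive_signals adds the magnitude channels and returns 18 signals", {
  cfg <- synthetic_config(n_subjects = 1, extended_signals = TRUE, seed = 3)
  rec <- generate_recording(cfg, "S01", "SQ")$recording
  out <- derive_signals(rec)
  expect_equal(names(out$channels), imu_channels(extended = TRUE))
  expect_length(out$channels, 18L)
  # 3-4-5 triangle
  rec$channels$acc_x[1:2] <- 3; rec$channels$acc_y[1:2] <- 4
  rec$channels$acc_z[1:2] <- 0
  expect_equal(derive_signals(rec)$channels$acc_mag[1:2], c(5, 5))
  # zero gyro -> zero magnitude
  rec$channels$gyro_x[] <- 0; rec$channels$gyro_y[] <- 0; rec$channels$gyro_z[] <- 0
  expect_true(all(derive_signals(rec)$channels$gyro_mag == 0))
  # missing orientation channels are named in the error
  raw <- generate_recording(synthetic_config(n_subjects = 1, seed = 3),
                            "S01", "SQ")$recording
  expect_error(derive_signals(raw), "quat_w")
})

test_that("feature matrices have signal x feature layout (342 and 114 columns)", {
  reps18 <- generated_repetitions(seed = 11, n_subjects = 1, reps_per_set = 2,
                                  extended = TRUE)
  fm <- feature_matrix(reps18)
  expect_equal(length(feature_columns(fm)), 18L * 19L)  # 342
  expect_equal(length(feature_columns(fm)), 342L)
  expect_false(anyNA(fm))
  expect_equal(feature_columns(fm)[1:2], c("acc_x.mean", "acc_x.rms"))
  expect_equal(feature_columns(fm)[20], "acc_y.mean")

  reps6 <- generated_repetitions(seed = 11, n_subjects = 1, reps_per_set = 2)
  fm6 <- feature_matrix(reps6)
  expect_equal(length(feature_columns(fm6)), 6L * 19L)  # 114

  # determinism: identical epochs give identical rows
  two <- feature_matrix(list(reps6[[1]], reps6[[1]]))
  expect_identical(as.numeric(two[1, feature_columns(two)]),
                   as.numeric(two[2, feature_columns(two)]))
  # heterogeneous channel sets are rejected
  expect_error(feature_matrix(list(reps18[[1]], reps6[[1]])), "heterogeneous")
})

test_that("order-independent features are invariant to time reversal", {
  set.seed(33)
  for (k in 1:5) {
    x <- stats::rnorm(250) + sin(2 * pi * 2 * (0:249) / 250)
    f <- compute_features(x)
    g <- compute_features(rev(x))
    invariant <- c("mean", "rms", "sd", "kurtosis", "median", "skewness",
                   "range", "variance", "max", "min", "energy", "p25", "p75",
                   "level_crossing_rate", "higuchi_fd")
    expect_equal(f[invariant], g[invariant], tolerance = 1e-9)
    # index features mirror: idx_rev = (n-1) - idx
    expect_equal(g[["idx_max"]], 249 - f[["idx_max"]])
    expect_equal(g[["idx_min"]], 249 - f[["idx_min"]])
    # periodized wavelet variances are only approximately reversal-invariant
    expect_equal(g[["wav_detail_var"]], f[["wav_detail_var"]], tolerance = 0.15)
  }
})
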