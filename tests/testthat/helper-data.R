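# Shared fixtures, built in code at test time.

# A tiny handmade recording with distinguishable channels.
make_toy_recording <- function(n = 300, fs = 51.2, subject = "T01", label = "SQ") {
  t <- (0:(n - 1)) / fs
  imu_recording(subject, label, list(
    acc_x = 0.5 * sin(2 * pi * 0.8 * t),
    acc_y = -3 * sin(pi * pmin(t / 3, 1))^2,
    acc_z = 9.81 + 0.1 * cos(2 * pi * 0.5 * t),
    gyro_x = 150 * sin(2 * pi * 0.4 * t),
    gyro_y = 40 * sin(2 * pi * 0.4 * t + 1),
    gyro_z = 10 * cos(2 * pi * 0.4 * t)), fs = fs)
}

# A repetition with the six panel channels at a fixed resampled length.
make_toy_repetition <- function(L = 250, label = "DL", subject = "T01",
                                rep_index = 1L) {
  tau <- seq(0, 1, length.out = L)
  rec <- imu_recording(subject, label, list(
    acc_x = c(0, 0.5 * sin(pi * tau), 0),
    acc_y = c(0, -8 * sin(pi * tau)^2, 0),
    acc_z = c(9.81, 9.81 - 6 * sin(pi * tau)^2, 9.81),
    gyro_x = c(0, 200 * sin(pi * tau)^2, 0),
    gyro_y = c(0, 20 * sin(pi * tau), 0),
    gyro_z = c(0, 15 * sin(pi * tau), 0)))
  r <- repetition(rec, 0L, as.integer(L / 2), L + 2L, rep_index = rep_index)
  resample_epoch(r, L)
}

# Segmented repetitions of one generated recording (memoised per arg set).
.fixture_env <- new.env(parent = emptyenv())

generated_repetitions <- function(seed = 11, n_subjects = 2, reps_per_set = 3,
                                  extended = FALSE) {
  key <- paste("reps", seed, n_subjects, reps_per_set, extended, sep = "-")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- synthetic_config(n_subjects = n_subjects, reps_per_set = reps_per_set,
                          seed = seed, extended_signals = extended)
  reps <- list()
  for (s in sprintf("S%02d", seq_len(n_subjects)))
    for (ex in cfg$exercises) {
      rec <- generate_recording(cfg, s, ex)$recording
      rec <- lowpass(rec)
      if (extended) rec <- derive_signals(rec)
      reps <- c(reps, segment_recording(rec)$repetitions)
    }
  .fixture_env[[key]] <- reps
  reps
}

# Independent brute-force local-maxima scan (oracle for peak counting):
# counts left-strict local maxima above a height threshold, so a two-sample
# plateau at a symmetric lobe top counts once.
brute_force_peaks <- function(x, height) {
  idx <- integer(0)
  for (i in 2:(length(x) - 1L))
    if (x[i - 1L] < x[i] && x[i + 1L] <= x[i] && x[i] >= height)
      idx <- c(idx, i)
  idx
}
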