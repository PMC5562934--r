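#' Synthetic-data generator configuration
#'
#' Parameters of the seeded generator that emulates repetition-structured,
#' lumbar-worn IMU recordings: each recording is one subject performing one
#' set of repetitions of a single exercise, with class-distinct waveform
#' templates, per-subject amplitude/tempo variability, per-repetition duration
#' jitter and additive sensor noise.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param reps_per_set Repetitions per set (default 10, one set of 10
#'   repetitions per exercise).
#' @param exercises Subset of [exercise_labels()].
#' @param fs Sampling rate in samples/s (default 51.2).
#' @param rep_duration_s Mean repetition duration in seconds (default 2.8).
#' @param duration_jitter Per-repetition uniform duration jitter fraction in
#'   `[0, 1)` (default 0.08).
#' @param gap_duration_s Mean low-activity gap between repetitions, seconds.
#' @param amplitude_jitter Per-subject multiplicative amplitude s.d. (default 0.15).
#' @param tempo_jitter Per-subject multiplicative tempo s.d. (default 0.1).
#' @param noise_sd Additive Gaussian noise s.d. per channel family, a named
#'   vector `c(acc=, gyro=, mag=, orient=)` in native units (m/s^2, deg/s, uT,
#'   rad). A single scalar is read as the gyroscope s.d. in deg/s with the
#'   other families scaled proportionally; `0` disables noise everywhere.
#' @param extended_signals Emit the full 18-channel set (magnetometer,
#'   magnitudes, quaternion, Euler angles) rather than the 6 raw channels.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 10L, reps_per_set = 10L,
                             exercises = exercise_labels(), fs = 51.2,
                             rep_duration_s = 2.8, duration_jitter = 0.08,
                             gap_duration_s = 1.2,
                             amplitude_jitter = 0.15, tempo_jitter = 0.1,
                             noise_sd = 2, extended_signals = FALSE,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, reps_per_set >= 1, fs > 0,
            rep_duration_s > 0, gap_duration_s > 0,
            duration_jitter >= 0, duration_jitter < 1,
            amplitude_jitter >= 0, amplitude_jitter < 1,
            tempo_jitter >= 0, tempo_jitter < 1)
  bad <- setdiff(exercises, exercise_labels())
  if (length(bad))
    stop("unknown exercise label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(names(noise_sd))) {
    stopifnot(length(noise_sd) == 1L, noise_sd >= 0)
    noise_sd <- noise_sd * c(acc = 0.075, gyro = 1, mag = 0.1, orient = 0.0025)
  } else {
    need <- c("acc", "gyro", "mag", "orient")
    if (!all(need %in% names(noise_sd)))
      stop("named `noise_sd` needs components: ", paste(need, collapse = ", "),
           call. = FALSE)
    stopifnot(all(noise_sd >= 0))
    noise_sd <- noise_sd[need]
  }
  structure(
    list(n_subjects = as.integer(n_subjects), reps_per_set = as.integer(reps_per_set),
         exercises = exercises, fs = fs, rep_duration_s = rep_duration_s,
         duration_jitter = duration_jitter, gap_duration_s = gap_duration_s,
         amplitude_jitter = amplitude_jitter, tempo_jitter = tempo_jitter,
         noise_sd = noise_sd, extended_signals = isTRUE(extended_signals),
         seed = as.integer(seed)),
    class = "synthetic_config")
}

## --- class waveform templates ------------------------------------------------

## Compact-support shape primitives on phase tau in [0, 1].
.lobe <- function(tau) sin(pi * tau)                  # half-sine, steep entry/exit
.hann <- function(tau) sin(pi * tau)^2                # smooth lobe, zero-slope ends
.burst <- function(tau, c, w)                         # narrow raised-cosine burst
  ifelse(abs(tau - c) < w, cos(pi * (tau - c) / (2 * w))^2, 0)

## Per-class raw-channel templates (deviations from rest baselines; gyro in
## deg/s, acc in m/s^2). Amplitudes sit inside the fixed plotting ranges
## (gyro_x within +-250 deg/s, acc_y/z within +-15 m/s^2). Each class has a
## distinct dominant gyroscope channel morphology: biphasic (SQ), asymmetric
## (LUL), single smooth lobe (DL), low-amplitude long lobe on gyro_y (SLSL),
## narrow high-amplitude burst (TJ).
.TEMPLATES <- list(
  SQ = list(dominant = "gyro_x", dur_scale = 1, orient_max = 0.9,
            axis = c(0.95, 0.2, 0.24),
            fun = function(tau) list(
              gyro_x = 180 * sin(2 * pi * tau),
              gyro_y = 30 * .lobe(tau),
              gyro_z = 20 * sin(2 * pi * tau),
              acc_x = 0.8 * sin(2 * pi * tau),
              acc_y = -6 * .hann(tau),
              acc_z = -4 * .hann(tau))),
  LUL = list(dominant = "gyro_x", dur_scale = 1, orient_max = 0.7,
             axis = c(0.78, 0.6, 0.18),
             fun = function(tau) list(
               gyro_x = 160 * sin(pi * tau^0.65),
               gyro_y = 60 * .lobe(tau),
               gyro_z = -25 * .lobe(tau),
               acc_x = 1.5 * sin(2 * pi * tau),
               acc_y = -5 * .hann(tau),
               acc_z = -3 * .hann(tau))),
  DL = list(dominant = "gyro_x", dur_scale = 1, orient_max = 1.1,
            axis = c(0.97, 0.15, 0.19),
            fun = function(tau) list(
              gyro_x = 200 * .hann(tau),
              gyro_y = 20 * .lobe(tau),
              gyro_z = 15 * .lobe(tau),
              acc_x = 0.5 * .lobe(tau),
              acc_y = -8 * .hann(tau),
              acc_z = -6 * .hann(tau))),
  SLSL = list(dominant = "gyro_y", dur_scale = 1.3, orient_max = 0.5,
              axis = c(0.15, 0.97, 0.19),
              fun = function(tau) list(
                gyro_x = 40 * .lobe(tau),
                gyro_y = 80 * .hann(tau),
                gyro_z = -30 * .hann(tau),
                acc_x = 1.0 * sin(2 * pi * tau),
                acc_y = -4 * .hann(tau),
                acc_z = -2.5 * .hann(tau))),
  TJ = list(dominant = "gyro_x", dur_scale = 0.7, orient_max = 0.4,
            axis = c(0.2, 0.25, 0.95),
            fun = function(tau) list(
              gyro_x = 230 * .burst(tau, 0.5, 0.2),
              gyro_y = 60 * .burst(tau, 0.45, 0.12) - 40 * .burst(tau, 0.65, 0.12),
              gyro_z = 35 * sin(2 * pi * tau),
              acc_x = 1.8 * sin(2 * pi * tau),
              acc_y = 10 * .burst(tau, 0.5, 0.15),
              acc_z = -3 * .hann(tau) + 5 * .burst(tau, 0.5, 0.1))))

## Rest baselines (sensor flat against the lumbar spine, z up).
.BASELINE <- c(acc_x = 0, acc_y = 0, acc_z = 9.81,
               gyro_x = 0, gyro_y = 0, gyro_z = 0)

#' Dominant gyroscope channel of a synthetic class template
#' @param exercise_label One of [exercise_labels()].
#' @return Channel name carrying the template's largest gyroscope lobe.
#' @export
template_dominant_channel <- function(exercise_label) {
  tpl <- .TEMPLATES[[exercise_label]]
  if (is.null(tpl)) stop("unknown exercise label '", exercise_label, "'", call. = FALSE)
  tpl$dominant
}

## Deterministic 31-bit string hash (seed derivation for per-subject streams).
.str_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h
}

## Evaluate expr under a temporary RNG state, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.subject_factors <- function(config, subject_id) {
  seed <- ((config$seed %% 100000) * 10007 + .str_hash(subject_id)) %% 2147483647
  .with_seed(seed, {
    amp <- max(0.2, 1 + stats::rnorm(1, 0, config$amplitude_jitter))
    tempo <- max(0.3, 1 + stats::rnorm(1, 0, config$tempo_jitter))
    list(amplitude = amp, tempo = tempo)
  })
}

#' Generate one synthetic IMU recording with ground truth
#'
#' Assembles `reps_per_set` instances of the class waveform template, separated
#' by low-activity gaps, applies the per-subject amplitude and tempo factors,
#' adds i.i.d. Gaussian noise per channel family, and (optionally) emits the
#' extended 18-channel set. The ground truth records, for every repetition, the
#' `(start, peak, end)` indices defined by the segmentation contract — the
#' dominant-channel peak and its adjacent zero crossings — computed on the
#' clean (noise-free) dominant channel.
#'
#' @param config A [synthetic_config()].
#' @param subject_id Subject identifier (drives the per-subject factors, so the
#'   same subject is self-consistent across exercises).
#' @param exercise_label One of [exercise_labels()].
#' @return List with elements `recording` (an `imu_recording`) and `truth`
#'   (a manifest `data.frame` of true start/peak/end, 0-based, half-open).
#' @export
generate_recording <- function(config, subject_id, exercise_label) {
  stopifnot(inherits(config, "synthetic_config"))
  tpl <- .TEMPLATES[[exercise_label]]
  if (is.null(tpl))
    stop("unknown exercise label '", exercise_label, "'", call. = FALSE)
  fac <- .subject_factors(config, subject_id)
  seed <- ((.str_hash(subject_id) * 131 + match(exercise_label, exercise_labels())) +
           (config$seed %% 100000) * 20011) %% 2147483647
  fs <- config$fs

  .with_seed(seed, {
    jit <- function(n, frac) 1 + stats::runif(n, -frac, frac)
    nrep <- config$reps_per_set
    dur_s <- config$rep_duration_s * tpl$dur_scale * fac$tempo *
      jit(nrep, config$duration_jitter)
    gap_s <- config$gap_duration_s * jit(nrep + 1L, config$duration_jitter)
    rep_len <- pmax(8L, as.integer(round(dur_s * fs)))
    gap_len <- pmax(4L, as.integer(round(gap_s * fs)))

    total <- sum(rep_len) + sum(gap_len)
    clean <- stats::setNames(
      rep(list(numeric(total)), length(.IMU_REQUIRED)), .IMU_REQUIRED)
    theta <- numeric(total)                    # orientation excursion, rad
    starts <- integer(nrep)                    # 0-based rep window starts
    pos <- gap_len[1L]                         # samples before first rep
    for (r in seq_len(nrep)) {
      n_i <- rep_len[r]
      tau <- (0:(n_i - 1L)) / (n_i - 1L)
      vals <- tpl$fun(tau)
      idx <- (pos + 1L):(pos + n_i)
      for (ch in .IMU_REQUIRED)
        clean[[ch]][idx] <- fac$amplitude * vals[[ch]]
      theta[idx] <- tpl$orient_max * fac$amplitude * .hann(tau)
      starts[r] <- pos
      pos <- pos + n_i + gap_len[r + 1L]
    }

    ## ground truth from the segmentation contract applied to the clean
    ## dominant channel (peak + adjacent zero crossings)
    dom <- clean[[tpl$dominant]]
    truth <- do.call(rbind, lapply(seq_len(nrep), function(r) {
      win <- (starts[r] + 1L):(starts[r] + rep_len[r])
      pk <- starts[r] + which.max(dom[win]) - 1L       # 0-based
      zc <- .zero_cross_bounds(dom, pk)
      data.frame(subject_id = subject_id, exercise_label = exercise_label,
                 repetition_index = r, start = zc[1L], peak = pk, end = zc[2L],
                 stringsAsFactors = FALSE)
    }))

    ## additive noise per channel family
    sdv <- config$noise_sd
    noisy <- clean
    for (ch in .IMU_REQUIRED) {
      fam <- if (startsWith(ch, "acc")) "acc" else "gyro"
      noisy[[ch]] <- clean[[ch]] + .BASELINE[[ch]] +
        stats::rnorm(total, 0, sdv[[fam]])
    }

    channels <- noisy
    if (config$extended_signals) {
      th <- theta + stats::rnorm(total, 0, sdv[["orient"]])
      ax <- tpl$axis / sqrt(sum(tpl$axis^2))
      channels$mag_x <- 25 * cos(theta) + stats::rnorm(total, 0, sdv[["mag"]])
      channels$mag_y <- 5 + 12 * sin(theta) + stats::rnorm(total, 0, sdv[["mag"]])
      channels$mag_z <- -40 + 10 * sin(theta) + stats::rnorm(total, 0, sdv[["mag"]])
      channels$acc_mag <- sqrt(noisy$acc_x^2 + noisy$acc_y^2 + noisy$acc_z^2)
      channels$gyro_mag <- sqrt(noisy$gyro_x^2 + noisy$gyro_y^2 + noisy$gyro_z^2)
      channels$quat_w <- cos(th / 2)
      channels$quat_x <- sin(th / 2) * ax[1L]
      channels$quat_y <- sin(th / 2) * ax[2L]
      channels$quat_z <- sin(th / 2) * ax[3L]
      deg <- 180 / pi
      channels$euler_pitch <- th * ax[1L] * deg
      channels$euler_roll <- th * ax[2L] * deg +
        stats::rnorm(total, 0, sdv[["orient"]] * deg)
      channels$euler_yaw <- th * ax[3L] * deg +
        stats::rnorm(total, 0, sdv[["orient"]] * deg)
    }

    rec <- imu_recording(subject_id, exercise_label, channels, fs = fs)
    list(recording = rec, truth = truth)
  })
}

## Zero-crossing bracket of a peak, 0-based half-open [start, end).
## A crossing is a consecutive-sample sign change; a value within
## 1e-9 * max|x| of 0 counts as a crossing sample. Scanning back from the
## peak, the bracket starts at the first sample of the non-negative side;
## scanning forward it ends (exclusive) at the first non-positive sample.
## Clamped to the series bounds when no crossing exists.
.zero_cross_bounds <- function(x, peak0) {
  n <- length(x)
  tol <- 1e-9 * max(abs(x))
  nonpos <- (x < 0) | (abs(x) <= tol)
  iszero <- abs(x) <= tol
  i <- peak0 + 1L                       # 1-based peak
  s <- 0L
  if (i > 1L) for (j in seq(i - 1L, 1L)) {
    if (nonpos[j]) { s <- if (iszero[j]) j - 1L else j; break }
  }
  e <- n
  if (i < n) for (j in seq(i + 1L, n)) {
    if (nonpos[j]) { e <- j - 1L; break }
  }
  c(s, e)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_subjects x length(exercises)` recordings via [write_recording()]
#' (CSV + JSON sidecar each) plus a ground-truth segment manifest
#' `ground_truth.csv`.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed). An existing non-empty
#'   directory is refused unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with `files` (data.frame of subject, exercise,
#'   path) and `truth` (the ground-truth manifest).
#' @export
generate_dataset <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  files <- list(); truth <- list()
  for (s in subjects) for (ex in config$exercises) {
    g <- generate_recording(config, s, ex)
    path <- file.path(out_dir, sprintf("%s_%s.csv", s, ex))
    write_recording(g$recording, path)
    files[[length(files) + 1L]] <- data.frame(
      subject_id = s, exercise_label = ex, path = path, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- g$truth
  }
  files <- do.call(rbind, files)
  truth <- do.call(rbind, truth)
  write_manifest(truth, file.path(out_dir, "ground_truth.csv"))
  invisible(list(files = files, truth = truth))
}
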