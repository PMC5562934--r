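#' Wavelet decomposition specification
#'
#' The engineered-feature set summarises each epoch's multilevel discrete
#' wavelet transform with the Daubechies-4 mother wavelet (8 taps) to level 7
#' under periodized extension, which keeps a level-7 decomposition valid for
#' 250-sample epochs.
#'
#' @param wavelet Only `"db4"` is provided.
#' @param level Decomposition level (default 7).
#' @return Object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(wavelet = "db4", level = 7L) {
  if (!identical(wavelet, "db4"))
    stop("only the Daubechies-4 ('db4') wavelet is provided", call. = FALSE)
  stopifnot(level >= 1)
  structure(list(wavelet = wavelet, level = as.integer(level)),
            class = "wavelet_spec")
}

## Daubechies-4 (8-tap) decomposition filters.
.DB4_LO <- c(-0.010597401785069032, 0.032883011666982945, 0.030841381835986965,
             -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
             0.7148465705525415, 0.23037781330885523)
.DB4_HI <- c(-0.23037781330885523, 0.7148465705525415, -0.6308807679295904,
             -0.02798376941698385, 0.18703481171888114, 0.030841381835986965,
             -0.032883011666982945, -0.010597401785069032)

## One periodized DWT step: odd-length input is extended by replicating its
## last sample, then analysis filters are applied by circular convolution and
## the outputs decimated by 2 (length ceiling(n/2)).
.dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2L) { x <- c(x, x[n]); n <- n + 1L }
  k2 <- 2L * seq_len(n %/% 2L) - 2L         # 0-based even output positions
  taps <- 0:7
  a <- vapply(k2, function(k)
    sum(.DB4_LO * x[((k + 4L - taps) %% n) + 1L]), numeric(1))
  d <- vapply(k2, function(k)
    sum(.DB4_HI * x[((k + 4L - taps) %% n) + 1L]), numeric(1))
  list(approx = a, detail = d)
}

#' Multilevel periodized db4 wavelet decomposition
#'
#' Mallat cascade: the one-step periodized analysis transform is applied
#' `level` times to the running approximation.
#'
#' @param x Numeric series.
#' @param spec A [wavelet_spec()].
#' @return List with `approx` (level-`level` approximation coefficients) and
#'   `details` (list of detail coefficient vectors, level 1 first).
#' @export
dwt_db4 <- function(x, spec = wavelet_spec()) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  details <- vector("list", spec$level)
  a <- x
  for (lev in seq_len(spec$level)) {
    s <- .dwt_step(a)
    details[[lev]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details)
}

#' Higuchi fractal dimension
#'
#' Curve-length-based fractal dimension estimate: for each scale `k` up to
#' `k_max`, the mean normalised length of the `k` decimated sub-curves is
#' computed, and the dimension is the negated slope of `log L(k)` against
#' `log k`.
#'
#' @param x Numeric series (length >= 2).
#' @param k_max Largest scale (default 10; reduced automatically so that the
#'   coarsest sub-curves of a short series keep at least two points).
#' @return Fractal dimension estimate (about 1 for smooth curves, up to about
#'   2 for noise-dominated ones); 0 for a constant series.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  n <- length(x)
  stopifnot(n >= 2L)
  k_max <- max(2L, min(as.integer(k_max), (n - 1L) %/% 2L))
  if (max(x) == min(x)) return(0)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_ <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      norm <- (n - 1) / ((length(idx) - 1L) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(lm_, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(lk) & lk > 0
  if (sum(ok) < 2L) return(0)
  -stats::coef(stats::lm(log(lk[ok]) ~ log(seq_len(k_max)[ok])))[[2L]]
}

#' Level crossing rate
#'
#' Fraction of consecutive-sample pairs in which the series crosses a
#' reference level (default: its mean): the count of strict sign changes of
#' `x - level` divided by `length(x) - 1`.
#'
#' @param x Numeric series (length >= 2).
#' @param level Reference level (default `mean(x)`).
#' @return Crossing rate in `[0, 1]`.
#' @export
level_crossing_rate <- function(x, level = mean(x)) {
  stopifnot(length(x) >= 2L)
  s <- x - level
  sum(s[-length(s)] * s[-1L] < 0) / (length(x) - 1L)
}

.FEATURE_NAMES <- c("mean", "rms", "sd", "kurtosis", "median", "skewness",
                    "range", "variance", "max", "idx_max", "min", "idx_min",
                    "energy", "p25", "p75", "level_crossing_rate",
                    "higuchi_fd", "wav_approx_var", "wav_detail_var")

#' Names of the 19 per-signal features
#' @return Character vector of the 19 feature names in canonical order.
#' @export
feature_names <- function() .FEATURE_NAMES

#' Compute the 19 engineered features of one epoch signal
#'
#' The fixed per-signal feature set of the comparator pipeline: mean, RMS,
#' standard deviation, kurtosis, median, skewness, range, variance, max,
#' index of max, min, index of min, energy (unnormalised sum of squares),
#' 25th and 75th percentiles, level crossing rate about the mean, Higuchi
#' fractal dimension (`k_max = 10`), and the variances of the wavelet
#' approximation coefficients (level 7) and of all detail coefficients
#' (levels 1-7 pooled) of a periodized db4 decomposition. Index features are
#' 0-based sample indices. For a constant epoch, kurtosis and skewness are
#' undefined and returned as 0 with a warning.
#'
#' @param x Numeric epoch series (length >= 2, conventionally 250).
#' @param wavelet A [wavelet_spec()].
#' @return Named numeric vector of 19 features.
#' @export
compute_features <- function(x, wavelet = wavelet_spec()) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (max(x) == min(x)) {
    warning("constant epoch: kurtosis and skewness undefined, returning 0")
    kur <- 0; skw <- 0
  } else {
    kur <- e1071::kurtosis(x)
    skw <- e1071::skewness(x)
  }
  w <- dwt_db4(x, wavelet)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  out <- c(mean(x), sqrt(mean(x^2)), stats::sd(x), kur, stats::median(x), skw,
           diff(range(x)), stats::var(x), max(x), which.max(x) - 1L, min(x),
           which.min(x) - 1L, sum(x^2), q[1L], q[2L], level_crossing_rate(x),
           higuchi_fd(x), stats::var(w$approx), stats::var(unlist(w$details)))
  stats::setNames(out, .FEATURE_NAMES)
}

#' Derive the canonical 18-signal set
#'
#' Adds the per-sample Euclidean magnitudes of acceleration (`acc_mag`) and
#' rotational velocity (`gyro_mag`) to a recording that already carries the
#' magnetometer, quaternion and Euler-angle channels, and returns the
#' recording with the canonical 18 channels in order.
#'
#' @param rec An `imu_recording` generated with extended signals.
#' @return The recording with all 18 canonical channels.
#' @export
derive_signals <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  ch <- rec$channels
  ch$acc_mag <- sqrt(ch$acc_x^2 + ch$acc_y^2 + ch$acc_z^2)
  ch$gyro_mag <- sqrt(ch$gyro_x^2 + ch$gyro_y^2 + ch$gyro_z^2)
  missing <- setdiff(.IMU_CHANNELS, names(ch))
  if (length(missing))
    stop("cannot derive the 18-signal set; missing channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  imu_recording(rec$subject_id, rec$exercise_label, ch[.IMU_CHANNELS],
                fs = rec$fs, quat_tol = Inf)
}

#' Feature matrix over a set of repetitions
#'
#' One row per repetition; feature columns are named `<signal>.<feature>` and
#' ordered canonical-signal-major (signal order x the 19-feature order), so a
#' full 18-signal epoch yields 342 feature values.
#'
#' @param reps List of `imu_repetition` objects sharing one channel set.
#' @param wavelet A [wavelet_spec()].
#' @return `data.frame` with `subject_id`, `exercise_label`, `rep_index`
#'   metadata columns followed by the feature columns.
#' @export
feature_matrix <- function(reps, wavelet = wavelet_spec()) {
  stopifnot(length(reps) >= 1L,
            all(vapply(reps, inherits, logical(1), "imu_repetition")))
  sets <- lapply(reps, function(r) names(r$channels))
  if (!all(vapply(sets, identical, logical(1), sets[[1L]])))
    stop("repetitions have heterogeneous channel sets", call. = FALSE)
  signals <- sets[[1L]]
  rows <- lapply(reps, function(r) {
    v <- unlist(lapply(signals, function(s) compute_features(r$channels[[s]], wavelet)))
    names(v) <- as.vector(outer(.FEATURE_NAMES, signals,
                                function(f, s) paste(s, f, sep = ".")))
    v
  })
  feat <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(data.frame(
    subject_id = vapply(reps, `[[`, character(1), "subject_id"),
    exercise_label = vapply(reps, `[[`, character(1), "exercise_label"),
    rep_index = vapply(reps, `[[`, integer(1), "rep_index"),
    stringsAsFactors = FALSE), feat)
}

#' Names of the feature columns of a feature matrix
#' @param features A `data.frame` from [feature_matrix()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "exercise_label", "rep_index"))
}
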