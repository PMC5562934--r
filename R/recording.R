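#' @keywords internal
"_PACKAGE"

## Canonical channel order. Feature columns, channel selection tie-breaks and
## CSV column order all follow this ordering.
.IMU_CHANNELS <- c(
  "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
  "mag_x", "mag_y", "mag_z", "acc_mag", "gyro_mag",
  "quat_w", "quat_x", "quat_y", "quat_z",
  "euler_pitch", "euler_roll", "euler_yaw"
)
.IMU_REQUIRED <- .IMU_CHANNELS[1:6]
.GYRO_CHANNELS <- c("gyro_x", "gyro_y", "gyro_z")
.QUAT_CHANNELS <- c("quat_w", "quat_x", "quat_y", "quat_z")

#' Exercise class labels
#'
#' The five lower-limb exercise classes recognised by the pipeline:
#' bodyweight squat (SQ), bodyweight lunge (LUL), barbell deadlift (DL),
#' single-leg squat (SLSL) and tuck jump (TJ).
#'
#' @return Character vector of the five class labels.
#' @export
exercise_labels <- function() c("SQ", "LUL", "DL", "SLSL", "TJ")

#' Canonical IMU channel names
#'
#' Fixed channel ordering used throughout the package: the six raw channels
#' (tri-axial accelerometer in m/s^2, tri-axial gyroscope in degrees/s),
#' optionally followed by magnetometer, acceleration/rotation magnitudes,
#' orientation quaternion and Euler angles (18 channels in total).
#'
#' @param extended If `TRUE` return all 18 channel names, otherwise the six
#'   required raw channels.
#' @return Character vector of channel names in canonical order.
#' @export
imu_channels <- function(extended = FALSE) {
  if (extended) .IMU_CHANNELS else .IMU_REQUIRED
}

#' Construct an IMU recording
#'
#' A recording holds the equal-length channel series of one subject performing
#' one set of a single exercise, together with its sampling rate. The required
#' channels are `acc_x`, `acc_y`, `acc_z` (m/s^2) and `gyro_x`, `gyro_y`,
#' `gyro_z` (degrees/s); the extended set adds magnetometer, magnitude,
#' quaternion and Euler-angle channels.
#'
#' @param subject_id Subject identifier string.
#' @param exercise_label One of [exercise_labels()].
#' @param channels Named list of equal-length numeric vectors. Channels are
#'   reordered into canonical order; unknown channel names are an error.
#' @param fs Sampling rate in samples/s (default 51.2).
#' @param quat_tol Tolerance for the unit-norm check on quaternion channels.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, exercise_label, channels, fs = 51.2,
                          quat_tol = 1e-6) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("`subject_id` must be a non-empty string", call. = FALSE)
  if (!exercise_label %in% exercise_labels())
    stop("unknown exercise label '", exercise_label, "'; expected one of ",
         paste(exercise_labels(), collapse = ", "), call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!is.list(channels) || is.null(names(channels)))
    stop("`channels` must be a named list of numeric vectors", call. = FALSE)

  unknown <- setdiff(names(channels), .IMU_CHANNELS)
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(.IMU_REQUIRED, names(channels))
  if (length(missing))
    stop("missing required channel(s): ", paste(missing, collapse = ", "), call. = FALSE)

  channels <- channels[intersect(.IMU_CHANNELS, names(channels))]
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channel series must have identical length", call. = FALSE)
  if (lens[[1]] < 2L)
    stop("channel series must have length >= 2", call. = FALSE)
  if (!all(vapply(channels, is.numeric, logical(1))))
    stop("all channels must be numeric", call. = FALSE)
  channels <- lapply(channels, as.numeric)

  if (all(.QUAT_CHANNELS %in% names(channels))) {
    nrm <- sqrt(channels$quat_w^2 + channels$quat_x^2 +
                channels$quat_y^2 + channels$quat_z^2)
    if (any(abs(nrm - 1) > quat_tol))
      stop("quaternion channels are not unit-norm (max deviation ",
           format(max(abs(nrm - 1))), ")", call. = FALSE)
  }

  structure(
    list(subject_id = subject_id, exercise_label = exercise_label,
         fs = fs, channels = channels),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- recording_length(x)
  cat(sprintf("<imu_recording> subject %s, exercise %s\n", x$subject_id, x$exercise_label))
  cat(sprintf("  %d channels x %d samples @ %.1f samples/s (%.1f s)\n",
              length(x$channels), n, x$fs, n / x$fs))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `imu_recording`.
#' @return Integer sample count.
#' @export
recording_length <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  length(rec$channels[[1]])
}

#' Construct a single-repetition epoch
#'
#' One segmented repetition of a recording. Sample indices are 0-based and the
#' epoch is the half-open window `[start, end)`; `peak` is the index of the
#' detected peak on the segmentation channel, with `start < peak < end`.
#'
#' @param recording The source `imu_recording`.
#' @param start,peak,end 0-based sample indices into the source recording.
#' @param rep_index 1-based repetition number within its set.
#' @return Object of class `imu_repetition` carrying the epoch slice of every
#'   channel plus source metadata.
#' @export
repetition <- function(recording, start, peak, end, rep_index = NA_integer_) {
  stopifnot(inherits(recording, "imu_recording"))
  n <- recording_length(recording)
  start <- as.integer(start); peak <- as.integer(peak); end <- as.integer(end)
  if (!(start < peak && peak < end && end <= n && start >= 0L))
    stop(sprintf("invalid epoch indices: need 0 <= start < peak < end <= %d, got (%d, %d, %d)",
                 n, start, peak, end), call. = FALSE)
  chans <- lapply(recording$channels, function(x) x[(start + 1L):end])
  structure(
    list(subject_id = recording$subject_id,
         exercise_label = recording$exercise_label,
         fs = recording$fs,
         start = start, peak = peak, end = end,
         rep_index = as.integer(rep_index),
         channels = chans,
         resampled_length = NULL),
    class = "imu_repetition")
}

#' @export
print.imu_repetition <- function(x, ...) {
  cat(sprintf("<imu_repetition> %s/%s rep %s: [%d, %d) peak %d, %d samples%s\n",
              x$subject_id, x$exercise_label,
              ifelse(is.na(x$rep_index), "?", x$rep_index),
              x$start, x$end, x$peak, length(x$channels[[1]]),
              if (is.null(x$resampled_length)) "" else
                sprintf(" (resampled to %d)", x$resampled_length)))
  invisible(x)
}

#' Build a segment manifest table
#'
#' One row per repetition: `(subject_id, exercise_label, repetition_index,
#' start, peak, end)` with 0-based, half-open `[start, end)` indices.
#' Rows belonging to one recording must be non-overlapping and sorted by
#' `start`.
#'
#' @param reps List of `imu_repetition` objects.
#' @return A `data.frame` manifest.
#' @export
segment_manifest <- function(reps) {
  stopifnot(all(vapply(reps, inherits, logical(1), "imu_repetition")))
  man <- data.frame(
    subject_id = vapply(reps, `[[`, character(1), "subject_id"),
    exercise_label = vapply(reps, `[[`, character(1), "exercise_label"),
    repetition_index = vapply(reps, `[[`, integer(1), "rep_index"),
    start = vapply(reps, `[[`, integer(1), "start"),
    peak = vapply(reps, `[[`, integer(1), "peak"),
    end = vapply(reps, `[[`, integer(1), "end"),
    stringsAsFactors = FALSE)
  .check_manifest(man)
  man
}

.check_manifest <- function(man) {
  need <- c("subject_id", "exercise_label", "repetition_index", "start", "peak", "end")
  if (!all(need %in% names(man)))
    stop("manifest is missing column(s): ",
         paste(setdiff(need, names(man)), collapse = ", "), call. = FALSE)
  for (key in split(man, paste(man$subject_id, man$exercise_label))) {
    key <- key[order(key$repetition_index), ]
    if (is.unsorted(key$start, strictly = TRUE))
      stop("manifest rows of one recording must be strictly increasing in start",
           call. = FALSE)
    if (any(key$start[-1] < key$end[-nrow(key)]))
      stop("manifest rows of one recording overlap", call. = FALSE)
  }
  invisible(man)
}
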