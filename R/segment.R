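#' Segmenter configuration
#'
#' Parameters of repetition segmentation: peaks are sought on the dominant
#' gyroscope channel, and each repetition spans the zero crossings adjacent to
#' a peak.
#'
#' @param channel Channel to segment on, or `"auto"` to pick the gyroscope
#'   channel with the largest peak-to-peak range ([select_channel()]).
#' @param min_peak_height Peak acceptance threshold as a fraction of the
#'   channel's maximum absolute value, in `(0, 1]` (default 0.5).
#' @param min_peak_separation_s Minimum separation between accepted peaks in
#'   seconds (default 1.0, about half an expected repetition duration).
#' @param resample_length Fixed epoch length after resampling (default 250);
#'   `NA` to skip resampling.
#' @param use_abs Detect peaks on `|signal|` instead of the signed signal, for
#'   exercises whose dominant lobe is negative.
#' @return Object of class `segmenter_config`.
#' @export
segmenter_config <- function(channel = "auto", min_peak_height = 0.5,
                             min_peak_separation_s = 1.0,
                             resample_length = 250L, use_abs = FALSE) {
  stopifnot(min_peak_height > 0, min_peak_height <= 1,
            min_peak_separation_s >= 0)
  if (!is.na(resample_length) && resample_length < 2)
    stop("`resample_length` must be >= 2 (or NA)", call. = FALSE)
  structure(list(channel = channel, min_peak_height = min_peak_height,
                 min_peak_separation_s = min_peak_separation_s,
                 resample_length = if (is.na(resample_length)) NA_integer_
                                   else as.integer(resample_length),
                 use_abs = isTRUE(use_abs)),
            class = "segmenter_config")
}

#' Select the dominant gyroscope channel
#'
#' Returns the gyroscope channel with the largest peak-to-peak range —
#' "amplitude" is read as peak-to-peak. Exact ties resolve to the first
#' channel in canonical order (`gyro_x`, `gyro_y`, `gyro_z`).
#'
#' @param rec An `imu_recording` (ideally already low-pass filtered).
#' @return The selected channel name.
#' @export
select_channel <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  rng <- vapply(.GYRO_CHANNELS,
                function(ch) diff(range(rec$channels[[ch]])), numeric(1))
  if (all(rng == 0))
    stop("degenerate recording: all gyroscope channels are constant", call. = FALSE)
  .GYRO_CHANNELS[which.max(rng)]   # which.max takes the first on ties
}

#' Detect single-repetition epochs on one channel
#'
#' Peaks are local maxima exceeding `min_peak_height * max(|signal|)` and
#' separated by at least `min_peak_separation_s`; when two candidate peaks are
#' closer than that, the higher one wins. Each accepted peak is bracketed by
#' its adjacent zero crossings: `start` is the nearest crossing at or before
#' the peak (clamped to 0 when the signal never crosses), `end` the nearest
#' crossing after it (clamped to the series length). A crossing is a
#' consecutive-sample sign change, with values within `1e-9 * max(|signal|)`
#' of zero counting as crossing samples; the epoch is half-open `[start, end)`
#' in 0-based indices and includes a leading zero sample but not a trailing
#' one. Returns an empty table for flat or sub-threshold signals.
#'
#' @param x Numeric series (a filtered channel).
#' @param fs Sampling rate in samples/s.
#' @param config A [segmenter_config()].
#' @return `data.frame` with 0-based columns `start`, `peak`, `end`, sorted and
#'   non-overlapping.
#' @export
detect_repetitions <- function(x, fs, config = segmenter_config()) {
  stopifnot(is.numeric(x), fs > 0)
  if (config$use_abs) x <- abs(x)
  n <- length(x)
  mx <- max(abs(x))
  empty <- data.frame(start = integer(0), peak = integer(0), end = integer(0))
  if (n < 3L || mx == 0) return(empty)
  h <- config$min_peak_height * mx

  ## local maxima above the height threshold (1-based candidate indices)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] >= h]
  if (!length(cand)) return(empty)

  ## enforce minimum separation, keeping higher peaks first
  min_sep <- config$min_peak_separation_s * fs
  keep <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  peaks <- sort(keep)

  eps <- lapply(peaks, function(p) .zero_cross_bounds(x, p - 1L))
  out <- data.frame(start = vapply(eps, `[[`, numeric(1), 1L),
                    peak = peaks - 1L,
                    end = vapply(eps, `[[`, numeric(1), 2L))
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  ## adjacent peaks sharing a lobe would yield overlapping brackets; trim
  if (nrow(out) > 1L)
    out$start[-1L] <- pmax(out$start[-1L], out$end[-nrow(out)])
  out[out$start < out$peak & out$peak < out$end, , drop = FALSE]
}

#' Segment a recording into repetitions
#'
#' Runs [select_channel()] (unless `config$channel` names one explicitly) and
#' [detect_repetitions()], slices every channel to each detected epoch, and
#' resamples each epoch to `config$resample_length`.
#'
#' @param rec An `imu_recording` (apply [lowpass()] first).
#' @param config A [segmenter_config()].
#' @return List with `repetitions` (list of `imu_repetition`), `manifest`
#'   (a segment manifest `data.frame`) and `channel` (the channel used).
#' @export
segment_recording <- function(rec, config = segmenter_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  ch <- if (identical(config$channel, "auto")) select_channel(rec) else config$channel
  if (!ch %in% names(rec$channels))
    stop("segmentation channel not present: ", ch, call. = FALSE)
  eps <- detect_repetitions(rec$channels[[ch]], rec$fs, config)
  reps <- lapply(seq_len(nrow(eps)), function(i) {
    r <- repetition(rec, eps$start[i], eps$peak[i], eps$end[i], rep_index = i)
    if (!is.na(config$resample_length)) r <- resample_epoch(r, config$resample_length)
    r
  })
  man <- if (length(reps)) segment_manifest(reps) else
    data.frame(subject_id = character(0), exercise_label = character(0),
               repetition_index = integer(0), start = integer(0),
               peak = integer(0), end = integer(0))
  list(repetitions = reps, manifest = man, channel = ch)
}

#' Resample an epoch to a fixed length
#'
#' Maps every channel of the epoch onto `L` uniformly spaced points spanning
#' it, by linear interpolation; the first and last samples are preserved
#' exactly, and resampling an `L`-length epoch to `L` is the identity.
#'
#' @param rep An `imu_repetition` with at least 2 samples.
#' @param L Target length (default 250).
#' @return The `imu_repetition` with every channel of length `L` and
#'   `resampled_length` set.
#' @export
resample_epoch <- function(rep, L = 250L) {
  stopifnot(inherits(rep, "imu_repetition"))
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("`L` must be an integer >= 2", call. = FALSE)
  n <- length(rep$channels[[1L]])
  if (n < 2L) stop("epoch too short to resample (need >= 2 samples)", call. = FALSE)
  grid <- seq(0, 1, length.out = n)
  out <- seq(0, 1, length.out = L)
  rep$channels <- lapply(rep$channels, function(y)
    stats::approx(grid, y, xout = out)$y)
  rep$resampled_length <- L
  rep
}
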