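#' Write an IMU recording to CSV (with JSON sidecar)
#'
#' The interchange format is a plain CSV with one column per channel (header =
#' channel names in canonical order) and one row per sample, plus a JSON
#' sidecar `<path>.json` holding `subject_id`, `exercise_label` and `fs`.
#'
#' @param rec An `imu_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write recording: directory does not exist: ", dir, call. = FALSE)
  df <- as.data.frame(rec$channels)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id,
               exercise_label = rec$exercise_label, fs = rec$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Reads a CSV written by [write_recording()]. Metadata comes from the JSON
#' sidecar when present; any of `subject_id`, `exercise_label`, `fs` given as
#' arguments override it.
#'
#' @param path CSV path (header row of channel names, numeric body).
#' @param subject_id,exercise_label,fs Optional metadata overrides.
#' @return An `imu_recording`.
#' @export
read_recording <- function(path, subject_id = NULL, exercise_label = NULL, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("recording file has no samples: ", path, call. = FALSE)
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric column(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  subject_id <- subject_id %||% meta$subject_id %||%
    sub("\\.csv$", "", basename(path))
  exercise_label <- exercise_label %||% meta$exercise_label
  fs <- fs %||% meta$fs %||% 51.2
  if (is.null(exercise_label))
    stop("no exercise label: pass `exercise_label` or provide a sidecar for ", path,
         call. = FALSE)
  imu_recording(subject_id, exercise_label, as.list(df), fs = as.numeric(fs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a segment manifest
#'
#' @param man Manifest `data.frame` (see [segment_manifest()]).
#' @param path CSV path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns the validated manifest `data.frame`.
#' @export
write_manifest <- function(man, path) {
  .check_manifest(man)
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_manifest(man)
  man
}
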