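#' Low-pass filter configuration
#'
#' Butterworth low-pass design used before segmentation. Defaults follow the
#' study protocol: cutoff 20 Hz, order 8. The filter can be applied zero-phase
#' (forward-backward, squaring the magnitude response but preserving zero
#' crossings and peak locations) or causally (single pass).
#'
#' @param fc Cutoff frequency in Hz (default 20).
#' @param order Filter order (default 8).
#' @param mode `"zero_phase"` (default) or `"causal"`.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(fc = 20, order = 8L, mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(fc > 0, order >= 1)
  structure(list(fc = fc, order = as.integer(order), mode = mode),
            class = "filter_config")
}

#' Low-pass filter every channel of a recording
#'
#' Applies the Butterworth low-pass of `config` (bilinear-transform design via
#' [signal::butter()], -3 dB at `fc`) to every channel. Length, metadata and
#' sampling rate are unchanged. In `zero_phase` mode the filter runs forward
#' and backward ([signal::filtfilt()]), so the effective amplitude response is
#' `|H(f)|^2` and no phase shift is introduced.
#'
#' @param rec An `imu_recording`.
#' @param config A [filter_config()] (default: 20 Hz, order 8, zero-phase).
#' @return The filtered `imu_recording`.
#' @export
lowpass <- function(rec, config = filter_config()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(config, "filter_config"))
  if (config$fc >= rec$fs / 2)
    stop(sprintf("cutoff fc = %g Hz must be below the Nyquist frequency %g Hz",
                 config$fc, rec$fs / 2), call. = FALSE)
  n <- recording_length(rec)
  if (n < 3L * config$order)
    stop(sprintf("series too short to filter: %d samples < 3 x order = %d",
                 n, 3L * config$order), call. = FALSE)
  bf <- signal::butter(config$order, config$fc / (rec$fs / 2), type = "low")
  channels <- lapply(rec$channels, .apply_butter, bf = bf, mode = config$mode)
  ## filtering does not exactly preserve quaternion unit norm at the series
  ## edges; revalidate with a relaxed tolerance
  imu_recording(rec$subject_id, rec$exercise_label, channels, fs = rec$fs,
                quat_tol = 1e-3)
}

## Single causal pass initialised at the first-sample steady state (the
## filter has unit DC gain, so filter(x) = filter(x - x[1]) + x[1]); this
## removes the start-up transient for series with a non-zero baseline.
.causal_pass <- function(x, bf) {
  as.numeric(signal::filter(bf, x - x[1L])) + x[1L]
}

## Zero-phase (forward-backward) pass with odd-reflection padding at both
## ends so edge transients fall inside the discarded pad. All steps are
## linear in x.
.zero_phase_pass <- function(x, bf) {
  n <- length(x)
  pad <- min(n - 1L, 100L)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- .causal_pass(xp, bf)
  y <- rev(.causal_pass(rev(y), bf))
  y[(pad + 1L):(pad + n)]
}

.apply_butter <- function(x, bf, mode) {
  switch(mode,
         zero_phase = .zero_phase_pass(x, bf),
         causal = .causal_pass(x, bf))
}

#' Analytic Butterworth magnitude response
#'
#' `|H(f)| = 1 / sqrt(1 + (f/fc)^(2 * order))` of the analog low-pass
#' prototype; the effective response of a zero-phase application is this
#' quantity squared. The discrete (bilinear) design matches it in the
#' passband and exactly at `fc` (-3 dB); in the transition band frequency
#' warping makes the discrete filter attenuate more strongly.
#'
#' @param f Frequencies in Hz.
#' @param config A [filter_config()].
#' @return Magnitude gain(s) in `[0, 1]`.
#' @export
butterworth_gain <- function(f, config = filter_config()) {
  g <- 1 / sqrt(1 + (f / config$fc)^(2 * config$order))
  if (config$mode == "zero_phase") g^2 else g
}
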