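# Study-scale synthetic conditions: 10 subjects x 5 exercises x 10
# repetitions at the generator's default (low) noise level. Memoised so the
# image-route and feature-route checks can share the generated recordings.

study_config <- function(seed, extended = FALSE) {
  synthetic_config(n_subjects = 10L, reps_per_set = 10L, seed = seed,
                   extended_signals = extended)
}

study_feature_table <- function(seed = 101) {
  key <- paste0("study-features-", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- study_config(seed, extended = TRUE)
  reps <- list()
  for (s in sprintf("S%02d", seq_len(cfg$n_subjects)))
    for (ex in cfg$exercises) {
      rec <- generate_recording(cfg, s, ex)$recording
      rec <- derive_signals(lowpass(rec))
      reps <- c(reps, segment_recording(rec)$repetitions)
    }
  .fixture_env[[key]] <- feature_matrix(reps)
  .fixture_env[[key]]
}
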