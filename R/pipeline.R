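#' End-to-end image-route pipeline on synthetic data
#'
#' Convenience driver for the full feature-free route under a subject-held-out
#' split: generate (or accept) recordings, low-pass filter, segment into
#' repetitions, render the six-panel images into a folder-per-label tree,
#' embed with the backbone, retrain the final softmax layer on the training
#' subjects, and evaluate on the held-out subjects' images.
#'
#' @param config A [synthetic_config()] describing the dataset.
#' @param holdout_subjects Subject ids (or count) to hold out for testing.
#' @param backbone An `imu_backbone` (default [tiny_cnn_backbone()]).
#' @param train_cfg A [train_config()].
#' @param filter_cfg A [filter_config()].
#' @param seg_cfg A [segmenter_config()].
#' @param spec A [plot_spec()].
#' @param work_dir Directory for the image tree (default: a temp dir).
#' @return List with `report` (an `evaluation_report` on held-out images),
#'   `curves`, `model`, `n_train`, `n_test`.
#' @export
run_image_pipeline <- function(config, holdout_subjects = 2L,
                               backbone = tiny_cnn_backbone(),
                               train_cfg = train_config(),
                               filter_cfg = filter_config(),
                               seg_cfg = segmenter_config(),
                               spec = plot_spec(),
                               work_dir = tempfile("imuvision-images-")) {
  stopifnot(inherits(config, "synthetic_config"))
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  if (is.numeric(holdout_subjects) && length(holdout_subjects) == 1L)
    holdout_subjects <- utils::tail(subjects, holdout_subjects)
  stopifnot(all(holdout_subjects %in% subjects),
            length(holdout_subjects) < length(subjects))

  reps_of <- function(subj) {
    out <- list()
    for (s in subj) for (ex in config$exercises) {
      rec <- generate_recording(config, s, ex)$recording
      seg <- segment_recording(lowpass(rec, filter_cfg), seg_cfg)
      out <- c(out, seg$repetitions)
    }
    out
  }
  train_subj <- setdiff(subjects, holdout_subjects)
  dir_train <- file.path(work_dir, "train")
  dir_test <- file.path(work_dir, "test")
  write_image_dataset(reps_of(train_subj), dir_train, spec)
  write_image_dataset(reps_of(holdout_subjects), dir_test, spec)

  btr <- compute_bottlenecks(dir_train, backbone, cache_dir = NULL)
  fit <- retrain_final_layer(btr$embeddings, btr$labels, train_cfg,
                             backbone_name = backbone$name)
  bte <- compute_bottlenecks(dir_test, backbone, cache_dir = NULL)
  pred <- predict(fit$model, bte$embeddings)
  report <- confusion_report(bte$labels, pred$labels,
                             labels = sort(unique(c(btr$labels, bte$labels))))
  list(report = report, curves = fit$curves, model = fit$model,
       n_train = nrow(btr$embeddings), n_test = nrow(bte$embeddings))
}

#' End-to-end feature-route pipeline on synthetic data
#'
#' The comparator route: generate extended-signal recordings, filter, segment,
#' derive the 18-signal set, compute the 342-value feature matrix and run
#' leave-one-subject-out cross-validation with the 400-tree random forest.
#'
#' @param config A [synthetic_config()] (must have `extended_signals = TRUE`).
#' @param n_trees Trees per fold (default 400).
#' @param seed Seed for the forest fits.
#' @param filter_cfg,seg_cfg,wavelet Stage configurations.
#' @return The [loso_cv()] result, plus `features` attached.
#' @export
run_feature_pipeline <- function(config, n_trees = 400L, seed = 1L,
                                 filter_cfg = filter_config(),
                                 seg_cfg = segmenter_config(),
                                 wavelet = wavelet_spec()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!config$extended_signals)
    stop("feature route needs `extended_signals = TRUE` in the config", call. = FALSE)
  reps <- list()
  for (s in sprintf("S%02d", seq_len(config$n_subjects)))
    for (ex in config$exercises) {
      rec <- generate_recording(config, s, ex)$recording
      rec <- derive_signals(lowpass(rec, filter_cfg))
      seg <- segment_recording(rec, seg_cfg)
      reps <- c(reps, seg$repetitions)
    }
  features <- feature_matrix(reps, wavelet)
  out <- loso_cv(features, n_trees = n_trees, seed = seed)
  out$features <- features
  out
}
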