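#' Train the random-forest comparator
#'
#' Fits a 400-tree random forest (via [randomForest::randomForest()]) on an
#' engineered-feature table. Prediction returns a class label and per-class
#' vote fractions summing to 1.
#'
#' @param features Feature `data.frame` from [feature_matrix()] (metadata
#'   columns are ignored for fitting), or a plain numeric matrix/data.frame.
#' @param labels Class labels (character or factor), one per row; taken from
#'   the `exercise_label` column when omitted and present.
#' @param n_trees Number of trees (default 400).
#' @param seed Integer seed; fixed seed gives identical fits.
#' @return Object of class `rf_model` wrapping the fitted forest and the label
#'   levels.
#' @export
train_random_forest <- function(features, labels = NULL, n_trees = 400L, seed = 1L) {
  if (is.null(labels)) {
    if (!"exercise_label" %in% names(features))
      stop("no `labels` given and no `exercise_label` column present", call. = FALSE)
    labels <- features$exercise_label
  }
  x <- as.data.frame(features)[, feature_columns(features), drop = FALSE]
  if (nrow(x) != length(labels)) stop("labels/features length mismatch", call. = FALSE)
  if (anyNA(x) || any(!vapply(x, function(c) all(is.finite(c)), logical(1))))
    stop("feature table contains missing or non-finite values", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("need at least 2 classes to train a classifier", call. = FALSE)
  fit <- .with_seed(as.integer(seed),
    randomForest::randomForest(x = x, y = labels, ntree = n_trees))
  structure(list(fit = fit, levels = levels(labels), n_trees = as.integer(n_trees)),
            class = "rf_model")
}

#' Predict with the random-forest comparator
#'
#' @param object An `rf_model`.
#' @param newdata Feature table (metadata columns ignored).
#' @param ... Unused.
#' @return List with `labels` (character) and `votes` (matrix of per-class
#'   vote fractions, rows summing to 1).
#' @export
predict.rf_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[, feature_columns(newdata), drop = FALSE]
  votes <- stats::predict(object$fit, x, type = "vote", norm.votes = TRUE)
  lab <- object$levels[max.col(votes, ties.method = "first")]
  list(labels = lab, votes = votes)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject in turn, trains on all other subjects and predicts the
#' held-out subject's repetitions; every repetition is predicted exactly once
#' and the pooled predictions form one confusion matrix.
#'
#' @param features Feature `data.frame` from [feature_matrix()] with
#'   `subject_id` and `exercise_label` columns.
#' @param n_trees Trees per fold (default 400).
#' @param seed Integer seed (each fold derives its own stream from it).
#' @param trainer Optional override: `function(train_features, train_labels,
#'   seed)` returning an object whose `predict(model, newdata)$labels` gives
#'   character labels. Defaults to the random forest above.
#' @return List with `report` (an `evaluation_report`, see
#'   [confusion_report()]), `predictions` (`data.frame` of subject, truth,
#'   prediction) and `folds` (held-out subject per fold).
#' @export
loso_cv <- function(features, n_trees = 400L, seed = 1L, trainer = NULL) {
  stopifnot(all(c("subject_id", "exercise_label") %in% names(features)))
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  if (is.null(trainer))
    trainer <- function(tr, lab, s) train_random_forest(tr, lab, n_trees = n_trees, seed = s)
  preds <- list()
  for (k in seq_along(subjects)) {
    held <- subjects[k]
    tr <- features[features$subject_id != held, , drop = FALSE]
    te <- features[features$subject_id == held, , drop = FALSE]
    if (!nrow(te)) { warning("subject with zero repetitions skipped: ", held); next }
    model <- trainer(tr, tr$exercise_label, as.integer(seed) + k)
    p <- predict(model, te)
    preds[[length(preds) + 1L]] <- data.frame(
      subject_id = held, truth = te$exercise_label, prediction = p$labels,
      stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)
  lev <- sort(unique(c(preds$truth, preds$prediction)))
  list(report = confusion_report(preds$truth, preds$prediction, lev),
       predictions = preds, folds = subjects)
}
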