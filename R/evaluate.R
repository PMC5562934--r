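#' Confusion matrix and derived metrics
#'
#' Builds the multi-class confusion matrix (rows = true class, columns =
#' predicted class) and its derived metrics: overall accuracy
#' (trace / total) and one-vs-rest per-class sensitivity
#' `TP / (TP + FN)` and specificity `TN / (TN + FP)`.
#'
#' @param truth,predicted Equal-length label vectors; every value must appear
#'   in `labels`.
#' @param labels Ordered class list fixing row/column order (default: sorted
#'   union of the observed labels).
#' @return Object of class `evaluation_report`: `labels`, `confusion`,
#'   `accuracy`, `sensitivity`, `specificity`, `n_examples`.
#' @export
confusion_report <- function(truth, predicted,
                             labels = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad))
    stop("label(s) not in `labels`: ", paste(bad, collapse = ", "), call. = FALSE)
  cm <- table(factor(truth, levels = labels), factor(predicted, levels = labels))
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(truth = labels, predicted = labels))
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  structure(
    list(labels = labels, confusion = cm,
         accuracy = sum(tp) / n,
         sensitivity = stats::setNames(tp / (tp + fn), labels),
         specificity = stats::setNames(tn / (tn + fp), labels),
         n_examples = n),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d examples, accuracy %.2f%%\n",
              x$n_examples, 100 * x$accuracy))
  print(x$confusion)
  m <- data.frame(sensitivity = round(x$sensitivity, 4),
                  specificity = round(x$specificity, 4))
  print(m)
  invisible(x)
}

#' Write an evaluation report (and training curves) to JSON
#'
#' The JSON round-trips losslessly through [read_report()]; a human-readable
#' summary (accuracy, one row of metrics per class, curve endpoints) is
#' printed when `verbose = TRUE`. Curves may be `NULL`
#' for routes without an iterative training phase.
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @param curves Optional training-curve `data.frame` from
#'   [retrain_final_layer()].
#' @param verbose Print the summary (default `TRUE`).
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, curves = NULL, verbose = TRUE) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(labels = report$labels,
              confusion = unname(apply(report$confusion, 1L, as.list)),
              accuracy = report$accuracy,
              sensitivity = as.list(report$sensitivity),
              specificity = as.list(report$specificity),
              n_examples = report$n_examples)
  if (!is.null(curves)) obj$curves <- curves
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (verbose) {
    print(report)
    if (!is.null(curves) && nrow(curves)) {
      last <- curves[nrow(curves), ]
      cat(sprintf("curves: %d logged steps; final train acc %.3f, val acc %.3f, cross entropy %.4f\n",
                  nrow(curves), last$train_accuracy, last$validation_accuracy,
                  last$cross_entropy))
    }
  }
  invisible(path)
}

#' @rdname render_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.character(obj$labels)
  cm <- matrix(as.integer(as.matrix(obj$confusion)), nrow = length(labels),
               dimnames = list(truth = labels, predicted = labels))
  rep <- structure(
    list(labels = labels, confusion = cm,
         accuracy = obj$accuracy,
         sensitivity = stats::setNames(unlist(obj$sensitivity), labels),
         specificity = stats::setNames(unlist(obj$specificity), labels),
         n_examples = as.integer(obj$n_examples)),
    class = "evaluation_report")
  if (!is.null(obj$curves)) attr(rep, "curves") <- as.data.frame(obj$curves)
  rep
}
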