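#' Tidy an evaluation report
#'
#' @param x An `eval_report` from [classification_report()] or [kfold_cv()].
#' @param ... Unused.
#' @return One row per class with precision, recall and F1 (full precision
#'   and display roundings).
#' @export
tidy.eval_report <- function(x, ...) {
  x$class_metrics
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy,
         error_rate = x$error_rate,
         n = x$n)
}

#' Tidy a fitted state classifier
#'
#' @param x A `state_svm` from [fit_state_classifier()].
#' @param ... Unused.
#' @return Per-class support-vector counts.
#' @export
tidy.state_svm <- function(x, ...) {
  tibble(class = x$levels,
         n_support_vectors = as.integer(x$fit$model$nSV))
}

#' @rdname tidy.state_svm
#' @export
glance.state_svm <- function(x, ...) {
  tibble(C = x$C, gamma = x$gamma, n_train = x$n_train,
         standardize = x$config$standardize,
         train_accuracy = x$train_accuracy)
}
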