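# Fixed class order for confusion matrices and reports.
report_levels <- c("baseline", "relax", "stress")

#' Classifier configuration
#'
#' Defaults follow the study configuration: a radial-basis-function SVM
#' with `C = 100` and `gamma = 10` on the five region temperatures in
#' degrees Celsius, evaluated by 5-fold cross-validation. Features are not
#' standardized by default (the stated `gamma` was chosen without a scaling
#' step); set `standardize = TRUE` to z-score features on the training
#' portion, since RBF kernels are scale-sensitive.
#'
#' @param C Soft-margin cost (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param standardize Z-score the five features using training-set
#'   statistics.
#' @param grid Optional list with numeric vectors `C` and `gamma`; when
#'   given, [fit_state_classifier()] grid-searches by grouped k-fold
#'   accuracy with a deterministic tie-break (smallest C, then smallest
#'   gamma).
#' @param group_folds Group cross-validation folds by participant (default)
#'   so no subject's frames appear on both sides of a fold; `FALSE` gives
#'   row-level folds, for comparison.
#' @param seed Integer seed controlling fold assignment and splits.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(C = 100, gamma = 10, k_folds = 5,
                              standardize = FALSE, grid = NULL,
                              group_folds = TRUE, seed = 1L) {
  stopifnot(C > 0, gamma > 0, k_folds >= 2)
  structure(list(C = C, gamma = gamma, k_folds = as.integer(k_folds),
                 standardize = standardize, grid = grid,
                 group_folds = group_folds, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Split a feature table by participant
#'
#' Randomly assigns whole participants to train or test so that no
#' subject's frames leak across the split (the study used 20 training and
#' 5 test participants, i.e. 240/60 frames).
#'
#' @param features A feature tibble from [extract_features()].
#' @param n_train,n_test Participant counts per side.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A list with tibbles `train` and `test`.
#' @export
split_by_participant <- function(features, n_train = 20, n_test = 5,
                                 seed = 1L) {
  ids <- sort(unique(features$participant_id))
  if (length(ids) < n_train + n_test) {
    stopf("need at least %d participants, have %d", n_train + n_test,
          length(ids))
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  train_ids <- shuffled[seq_len(n_train)]
  test_ids <- shuffled[n_train + seq_len(n_test)]
  list(train = dplyr::filter(features, .data$participant_id %in% train_ids),
       test = dplyr::filter(features, .data$participant_id %in% test_ids))
}

# Participant-grouped (or row-level) fold assignment; returns an integer
# fold id per row. Refolds with a perturbed seed (up to max_attempts) if
# some fold's training portion would miss a class.
make_folds <- function(features, k, seed, group = TRUE, max_attempts = 10L) {
  for (attempt in seq_len(max_attempts)) {
    s <- seed + (attempt - 1L)
    fold <- if (group) {
      ids <- sort(unique(features$participant_id))
      assign <- withr::with_seed(s, sample(rep_len(seq_len(k), length(ids))))
      assign[match(features$participant_id, ids)]
    } else {
      withr::with_seed(s, sample(rep_len(seq_len(k), nrow(features))))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(features$phase[fold != f])) == length(unique(features$phase))
    }, logical(1)))
    if (ok) {
      if (attempt > 1L) {
        warn(sprintf("refolded %d time(s) so every training fold sees all classes",
                     attempt - 1L))
      }
      return(fold)
    }
  }
  stopf("could not build folds with every class in every training portion")
}

fit_svm_raw <- function(train, C, gamma, standardize) {
  x <- as.matrix(train[, roi_names()])
  y <- factor(train$phase, report_levels)
  center <- scale_sd <- NULL
  if (standardize) {
    center <- colMeans(x)
    scale_sd <- apply(x, 2, sd)
    x <- scale(x, center, scale_sd)
  }
  model <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
  list(model = model, center = center, scale_sd = scale_sd)
}

predict_svm_raw <- function(fit, newdata) {
  x <- as.matrix(newdata[, roi_names()])
  if (!is.null(fit$center)) x <- scale(x, fit$center, fit$scale_sd)
  predict(fit$model, x)
}

grouped_cv_accuracy <- function(features, C, gamma, config) {
  fold <- make_folds(features, config$k_folds, config$seed,
                     group = config$group_folds)
  pred <- character(nrow(features))
  for (f in sort(unique(fold))) {
    fit <- fit_svm_raw(features[fold != f, ], C, gamma, config$standardize)
    pred[fold == f] <- as.character(predict_svm_raw(fit, features[fold == f, ]))
  }
  mean(pred == features$phase)
}

#' Train the three-state SVM
#'
#' Fits a multiclass RBF-SVM mapping the five region temperatures to the
#' baseline/stress/relax label. When `config$grid` is set, every (C, gamma)
#' candidate pair is scored by grouped k-fold accuracy and the best is
#' selected, breaking ties toward the smallest C, then the smallest gamma.
#'
#' @param features Training feature tibble (must contain at least two
#'   classes).
#' @param config A [classifier_config()].
#' @return An object of class `state_svm`.
#' @export
fit_state_classifier <- function(features, config = classifier_config()) {
  if (dplyr::n_distinct(features$phase) < 2L) {
    stopf("training data must contain at least two classes")
  }
  C <- config$C; gamma <- config$gamma; grid_scores <- NULL
  if (!is.null(config$grid)) {
    cand <- expand.grid(C = sort(config$grid$C),
                        gamma = sort(config$grid$gamma))
    cand$accuracy <- purrr::map2_dbl(cand$C, cand$gamma, function(C, g) {
      grouped_cv_accuracy(features, C, g, config)
    })
    # ties break toward smallest C, then smallest gamma: rows are already
    # ordered that way, and which.max takes the first maximum
    cand <- cand[order(cand$C, cand$gamma), ]
    best <- cand[which.max(cand$accuracy), ]
    C <- best$C; gamma <- best$gamma
    grid_scores <- as_tibble(cand)
  }
  fit <- fit_svm_raw(features, C, gamma, config$standardize)
  structure(
    list(fit = fit, C = C, gamma = gamma, config = config,
         grid_scores = grid_scores,
         n_train = nrow(features),
         levels = report_levels,
         train_accuracy = mean(predict_svm_raw(fit, features) ==
                                 features$phase)),
    class = "state_svm"
  )
}

#' Predict stress states for new frames
#'
#' @param object A fitted `state_svm`.
#' @param newdata Tibble with the five region-temperature columns (any
#'   column order; matched by name). Missing or non-finite features are an
#'   error.
#' @param ... Unused.
#' @return Factor of labels in `baseline`/`relax`/`stress`.
#' @export
predict.state_svm <- function(object, newdata, ...) {
  missing <- setdiff(roi_names(), names(newdata))
  if (length(missing) > 0L) {
    stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
  }
  x <- as.matrix(newdata[, roi_names()])
  if (anyNA(x) || any(!is.finite(x))) {
    stopf("non-finite feature values")
  }
  predict_svm_raw(object$fit, newdata)
}

#' @export
print.state_svm <- function(x, ...) {
  cat(sprintf(
    "<state_svm> RBF SVM, C=%g gamma=%g, %d training frames, training accuracy %.1f%%\n",
    x$C, x$gamma, x$n_train, 100 * x$train_accuracy))
  invisible(x)
}

#' k-fold cross-validated evaluation
#'
#' Splits the table into k folds (grouped by participant by default), fits
#' the SVM on each training portion, predicts the held-out fold, pools all
#' held-out predictions, and reports a single confusion matrix with its
#' derived metrics.
#'
#' @inheritParams fit_state_classifier
#' @return An `eval_report` (see [classification_report()]) with the pooled
#'   predictions in attribute `predictions`.
#' @export
kfold_cv <- function(features, config = classifier_config()) {
  fold <- make_folds(features, config$k_folds, config$seed,
                     group = config$group_folds)
  pred <- character(nrow(features))
  for (f in sort(unique(fold))) {
    train <- features[fold != f, ]
    model <- fit_state_classifier(
      train, classifier_config(C = config$C, gamma = config$gamma,
                               k_folds = config$k_folds,
                               standardize = config$standardize,
                               grid = config$grid,
                               group_folds = config$group_folds,
                               seed = config$seed))
    pred[fold == f] <- as.character(predict(model, features[fold == f, ]))
  }
  cm <- confusion_matrix(features$phase, pred)
  report <- classification_report(cm)
  attr(report, "predictions") <- tibble(
    frame_id = features$frame_id, truth = features$phase,
    predicted = pred, fold = fold)
  report
}
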