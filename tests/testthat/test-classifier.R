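# well-separated three-cluster table for exactness checks
separated_features <- function(n_subjects = 6, frames_per_phase = 3) {
  centers <- list(baseline = c(33, 35, 34.5, 35.5, 34.5),
                  stress = c(31, 33.5, 33, 34, 33.5),
                  relax = c(35, 36.5, 36, 37, 35.5))
  rows <- list()
  withr::with_seed(41, {
    for (s in seq_len(n_subjects)) {
      for (phase in names(centers)) {
        for (i in seq_len(frames_per_phase)) {
          v <- centers[[phase]] + rnorm(5, 0, 0.05)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            participant_id = sprintf("P%02d", s),
            frame_id = sprintf("P%02d_%s_%d", s, phase, i),
            phase = phase, nose = v[1], right_cheek = v[2],
            left_cheek = v[3], forehead = v[4], chin = v[5])
        }
      }
    }
  })
  dplyr::bind_rows(rows)
}

test_that("participant splits are disjoint, exhaustive, and seeded", {
  table <- generate_feature_table(synth_config(seed = 8))
  split <- split_by_participant(table, n_train = 20, n_test = 5, seed = 3)
  expect_equal(nrow(split$train), 240L)
  expect_equal(nrow(split$test), 60L)
  expect_length(intersect(split$train$participant_id,
                          split$test$participant_id), 0)
  expect_setequal(c(split$train$frame_id, split$test$frame_id),
                  table$frame_id)
  split2 <- split_by_participant(table, n_train = 20, n_test = 5, seed = 3)
  expect_identical(split$train$frame_id, split2$train$frame_id)
  expect_error(split_by_participant(table, n_train = 24, n_test = 5),
               "participants")
})

test_that("the SVM separates well-separated clusters and is deterministic", {
  feats <- separated_features()
  model <- fit_state_classifier(feats)
  expect_equal(model$train_accuracy, 1)
  model2 <- fit_state_classifier(feats)
  expect_identical(as.character(predict(model, feats)),
                   as.character(predict(model2, feats)))
  # training rows re-predict their own label
  expect_equal(as.character(predict(model, feats)), feats$phase)

  single <- feats[feats$phase == "baseline", ]
  expect_error(fit_state_classifier(single), "two classes")
})

test_that("prediction is schema-driven: column order irrelevant, batch = per-row", {
  feats <- separated_features()
  model <- fit_state_classifier(feats)
  reordered <- feats[, c("chin", "forehead", "left_cheek", "right_cheek",
                         "nose", "phase", "participant_id", "frame_id")]
  expect_identical(as.character(predict(model, reordered)),
                   as.character(predict(model, feats)))
  batch <- as.character(predict(model, feats))
  per_row <- vapply(seq_len(nrow(feats)), function(i) {
    as.character(predict(model, feats[i, ]))
  }, character(1))
  expect_identical(batch, per_row)
  expect_error(predict(model, feats[, c("nose", "chin")]), "missing feature")
})

test_that("grid search picks the accuracy argmax with smallest-C tie-break", {
  feats <- separated_features()
  config <- classifier_config(grid = list(C = c(1, 100), gamma = c(0.1, 10)),
                              k_folds = 3, seed = 2)
  model <- fit_state_classifier(feats, config)
  scores <- model$grid_scores
  expect_equal(nrow(scores), 4L)
  # oracle: recompute the exhaustive grid independently and apply the
  # tie-break (smallest C, then smallest gamma, among the maxima)
  best <- scores[scores$accuracy == max(scores$accuracy), ]
  best <- best[order(best$C, best$gamma), ][1, ]
  expect_equal(model$C, best$C)
  expect_equal(model$gamma, best$gamma)
})

test_that("leave-one-subject-out cross-validation equals a brute-force loop", {
  feats <- separated_features(n_subjects = 5, frames_per_phase = 2)
  n_sub <- 5L
  config <- classifier_config(k_folds = n_sub, seed = 1)
  report <- kfold_cv(feats, config)
  preds <- attr(report, "predictions")

  # brute force: hold out each subject in turn
  manual <- character(nrow(feats))
  for (sub in unique(feats$participant_id)) {
    idx <- feats$participant_id == sub
    fit <- fit_state_classifier(feats[!idx, ], config)
    manual[idx] <- as.character(predict(fit, feats[idx, ]))
  }
  expect_identical(preds$predicted, manual)
  expect_equal(report$overall_accuracy, 100 * mean(manual == feats$phase))
})

test_that("confusion matrices count in fixed class order", {
  truth <- c("baseline", "baseline", "relax", "stress")
  pred <- c("baseline", "relax", "relax", "stress")
  cm <- confusion_matrix(truth, pred)
  expect_equal(unname(diag(cm)), c(1, 1, 1))
  expect_equal(cm["baseline", "relax"], 1)
  expect_equal(sum(cm), 4)

  perfect <- confusion_matrix(rep(c("baseline", "relax", "stress"), 4),
                              rep(c("baseline", "relax", "stress"), 4))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))

  all_relax <- confusion_matrix(rep(c("baseline", "relax", "stress"), 2),
                                rep("relax", 6))
  expect_true(all(all_relax[, c("baseline", "stress")] == 0))

  withr::with_seed(43, {
    t50 <- sample(c("baseline", "relax", "stress"), 50, replace = TRUE)
    p50 <- sample(c("baseline", "relax", "stress"), 50, replace = TRUE)
  })
  cm50 <- confusion_matrix(t50, p50)
  for (a in c("baseline", "relax", "stress")) {
    for (b in c("baseline", "relax", "stress")) {
      expect_equal(cm50[a, b], sum(t50 == a & p50 == b))
    }
  }
  expect_error(confusion_matrix(c("baseline"), c("happy")), "unknown label")
  expect_error(confusion_matrix(c("baseline"), c("relax", "stress")),
               "length")
})

test_that("classification reports agree with a tally oracle", {
  withr::with_seed(44, {
    truth <- sample(c("baseline", "relax", "stress"), 120, replace = TRUE)
    pred <- ifelse(runif(120) < 0.75, truth,
                   sample(c("baseline", "relax", "stress"), 120,
                          replace = TRUE))
  })
  report <- classification_report(confusion_matrix(truth, pred))
  oracle <- oracle_report(truth, pred)
  for (cls in c("baseline", "relax", "stress")) {
    row <- report$class_metrics[report$class_metrics$class == cls, ]
    expect_equal(row$precision, oracle[[cls]][["precision"]])
    expect_equal(row$recall, oracle[[cls]][["recall"]])
    expect_equal(row$f1, oracle[[cls]][["f1"]])
  }
  expect_equal(report$overall_accuracy, oracle$accuracy)
  expect_equal(report$overall_accuracy + report$error_rate, 100)

  identity_cm <- diag(c(10, 12, 9))
  rep_id <- classification_report(identity_cm)
  expect_true(all(rep_id$class_metrics$f1 == 100))
  expect_equal(rep_id$overall_accuracy, 100)

  # a class with no predictions: precision undefined, flagged, not zero
  cm0 <- rbind(c(0, 5, 0), c(0, 10, 0), c(0, 4, 6))
  expect_warning(rep0 <- classification_report(cm0), "precision undefined")
  expect_true(is.na(rep0$class_metrics$precision[1]))
})

test_that("duplicating training rows barely moves the decision surface", {
  feats <- separated_features()
  model <- fit_state_classifier(feats)
  doubled <- dplyr::bind_rows(feats, feats)
  model2 <- fit_state_classifier(doubled)
  grid <- generate_feature_table(synth_config(n_subjects = 10, seed = 9))
  agreement <- mean(as.character(predict(model, grid)) ==
                      as.character(predict(model2, grid)))
  expect_gte(agreement, 0.99)
})

test_that("label permutation drives pooled CV accuracy to chance", {
  table <- generate_feature_table(synth_config("separable", seed = 10))
  permuted <- table
  withr::with_seed(45, {
    permuted$phase <- sample(permuted$phase)
  })
  report <- kfold_cv(permuted, classifier_config(seed = 10))
  expect_gte(report$overall_accuracy / 100, 0.20)
  expect_lte(report$overall_accuracy / 100, 0.47)
})
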