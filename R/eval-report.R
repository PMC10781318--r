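#' Confusion matrix in fixed class order
#'
#' @param y_true,y_pred Equal-length label vectors over
#'   `baseline`/`relax`/`stress`.
#' @return 3x3 integer matrix, rows = true class, columns = predicted, in
#'   the fixed order baseline, relax, stress.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stopf("label sequences differ in length")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), report_levels)
  if (length(bad) > 0L) {
    stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  }
  table(factor(y_true, report_levels), factor(y_pred, report_levels)) |>
    unclass() |>
    matrix(3, 3, dimnames = list(true = report_levels,
                                 predicted = report_levels))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; inputs and output on the same scale
#' (both as proportions or both as percentages). Returns `NA` when both are
#' zero.
#'
#' @param precision,recall Numeric vectors.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Classification report from a confusion matrix
#'
#' Computes per-class precision (`diag/colsum`), recall (`diag/rowsum`) and
#' F1, plus overall accuracy (`100 * trace / total`) and the complementary
#' error rate. Percentages are kept at full precision; the `class_metrics`
#' tibble also carries the conventional display roundings: recall to two
#' decimals (`recall_2dp`, the per-class "accuracy" figure) and precision,
#' recall and F1 to integer percent. A class that received no predictions
#' has undefined precision, reported as `NA` with a warning rather than 0.
#'
#' @param cm A 3x3 confusion matrix from [confusion_matrix()].
#' @return An object of class `eval_report`: a list with `confusion`,
#'   `class_metrics` (tibble), `overall_accuracy`, `error_rate` and `n`.
#' @export
classification_report <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0L) stopf("empty confusion matrix")
  diagv <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  if (any(colsum == 0)) {
    warn(sprintf("no predictions for class(es) %s; precision undefined",
                 paste(rownames(cm)[colsum == 0], collapse = ", ")))
  }
  precision <- unname(ifelse(colsum == 0, NA_real_, 100 * diagv / colsum))
  recall <- unname(ifelse(rowsum == 0, NA_real_, 100 * diagv / rowsum))
  f1 <- f1_score(precision, recall)
  metrics <- tibble(
    class = rownames(cm) %||% report_levels,
    n_true = as.integer(rowsum),
    precision = precision,
    recall = recall,
    f1 = f1,
    recall_2dp = round(recall, 2),
    precision_pct = round(precision),
    recall_pct = round(recall),
    f1_pct = round(f1)
  )
  accuracy <- 100 * sum(diagv) / total
  structure(
    list(confusion = cm, class_metrics = metrics,
         overall_accuracy = accuracy, error_rate = 100 - accuracy,
         n = total),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d frames, overall accuracy %.2f%% (error rate %.2f%%)\n",
              x$n, x$overall_accuracy, x$error_rate))
  print(x$confusion)
  m <- x$class_metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-9s recall %6.2f%%  precision %3.0f%%  F1 %3.0f%%\n",
                m$class[i], m$recall_2dp[i], m$precision_pct[i], m$f1_pct[i]))
  }
  invisible(x)
}

# display-rounding matchers for reconstruct_confusion: a printed 2-dp
# percentage may come from rounding or truncation (18/19 = 94.736... is
# printed as 94.73), so both are accepted.
matches_2dp <- function(value, printed) {
  abs(round(value, 2) - printed) < 0.005 |
    abs(floor(value * 100) / 100 - printed) < 0.005
}

#' Reconstruct a confusion matrix from printed per-class metrics
#'
#' Exhaustively searches small-integer 3x3 confusion matrices whose
#' per-class recall (to two decimals, rounding or truncation) and integer
#' per-class precision match a printed metrics table, given the total
#' evaluation count. Useful for recovering the full matrix, and hence the
#' overall accuracy, from a published report.
#'
#' @param recall_2dp Numeric length-3: per-class recall percentages to two
#'   decimals, in baseline/relax/stress order.
#' @param precision_pct Numeric length-3: per-class precision percentages
#'   rounded to integers.
#' @param total Total evaluation frames.
#' @param max_class_n Upper bound on any class's true count in the search.
#' @return A list with `matrices` (all consistent matrices), `unique`
#'   (logical), and — when unique — `confusion` and its `report` from
#'   [classification_report()].
#' @export
reconstruct_confusion <- function(recall_2dp, precision_pct, total = 66,
                                  max_class_n = 40) {
  stopifnot(length(recall_2dp) == 3, length(precision_pct) == 3)
  # feasible (row total, diagonal) pairs per class from the recall figure
  row_options <- lapply(1:3, function(cls) {
    out <- list()
    for (n in 1:max_class_n) {
      for (d in 0:n) {
        if (matches_2dp(100 * d / n, recall_2dp[cls])) {
          out[[length(out) + 1L]] <- c(n = n, d = d)
        }
      }
    }
    out
  })
  found <- list()
  for (r1 in row_options[[1]]) for (r2 in row_options[[2]]) {
    n3 <- total - r1[["n"]] - r2[["n"]]
    if (n3 < 1 || n3 > max_class_n) next
    for (r3 in row_options[[3]]) {
      if (r3[["n"]] != n3) next
      e1 <- r1[["n"]] - r1[["d"]]; e2 <- r2[["n"]] - r2[["d"]]
      e3 <- r3[["n"]] - r3[["d"]]
      for (a in 0:e1) for (b in 0:e2) for (c in 0:e3) {
        cm <- rbind(c(r1[["d"]], a, e1 - a),
                    c(b, r2[["d"]], e2 - b),
                    c(c, e3 - c, r3[["d"]]))
        colsum <- colSums(cm)
        if (any(colsum == 0)) next
        prec <- 100 * diag(cm) / colsum
        if (all(round(prec) == precision_pct)) {
          dimnames(cm) <- list(true = report_levels,
                               predicted = report_levels)
          found[[length(found) + 1L]] <- cm
        }
      }
    }
  }
  found <- unique(found)
  res <- list(matrices = found, unique = length(found) == 1L)
  if (res$unique) {
    res$confusion <- found[[1]]
    res$report <- classification_report(found[[1]])
  }
  res
}

#' Export an evaluation report
#'
#' Writes the per-class metrics as CSV and the full report (confusion
#' matrix included) as JSON.
#'
#' @param report An `eval_report`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    readr::write_csv(report$class_metrics, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(confusion = report$confusion,
           class_metrics = report$class_metrics,
           overall_accuracy = report$overall_accuracy,
           error_rate = report$error_rate, n = report$n),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
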