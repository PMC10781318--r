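state_levels_ordered <- c("baseline", "stress", "relax")

#' Per-region, per-state temperature summary
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of each
#' region's temperature within each protocol state, across all frames.
#'
#' @param features A feature tibble from [extract_features()] (columns
#'   `participant_id`, `phase`, and the five regions of [roi_names()]).
#' @return A tibble with columns `roi`, `phase`, `mean`, `sd`, `n`.
#' @export
summarize_by_state <- function(features) {
  if (nrow(features) == 0L) stopf("empty feature table")
  long <- tidyr::pivot_longer(features, dplyr::all_of(roi_names()),
                              names_to = "roi", values_to = "temp")
  out <- long |>
    dplyr::group_by(.data$roi, .data$phase) |>
    dplyr::summarise(mean = mean(.data$temp), sd = sd(.data$temp),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2L)) {
    stopf("a phase has fewer than 2 rows; SD is undefined")
  }
  out$roi <- factor(out$roi, roi_names())
  out$phase <- factor(out$phase, state_levels_ordered)
  dplyr::arrange(out, .data$roi, .data$phase)
}

#' Per-subject, per-phase mean temperatures
#'
#' Averages each participant's frames within each phase (the protocol takes
#' four frames at the end of each stage), producing the subject-level block
#' data used by the repeated-measures test.
#'
#' @inheritParams summarize_by_state
#' @param allow_unbalanced If `FALSE` (default), every participant must
#'   contribute the same number of frames to every phase.
#' @return A tibble with columns `participant_id`, `phase`, and the five
#'   region means.
#' @export
per_subject_phase_means <- function(features, allow_unbalanced = FALSE) {
  counts <- dplyr::count(features, .data$participant_id, .data$phase)
  if (!allow_unbalanced && dplyr::n_distinct(counts$n) > 1L) {
    stopf("unbalanced design: frame counts per participant x phase differ %s",
          "(set allow_unbalanced = TRUE to override)")
  }
  features |>
    dplyr::group_by(.data$participant_id, .data$phase) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(roi_names()), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$phase)
}

#' Friedman repeated-measures rank test
#'
#' Nonparametric test for differences among k matched conditions. Values
#' are ranked within each block (ties get mean ranks) and the tie-corrected
#' statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (A - C)}
#' is referred to a chi-square distribution with k - 1 degrees of freedom,
#' where \eqn{R_j} are rank column sums, \eqn{A} the sum of squared ranks
#' and \eqn{C = nk(k+1)^2/4}. Without ties this reduces to the familiar
#' \eqn{12/(nk(k+1)) \sum R_j^2 - 3n(k+1)}. Blocks that are entirely tied
#' carry no information; if every block is fully tied, `Q = 0` and `p = 1`.
#'
#' @param block_matrix Numeric matrix, one row per block (subject), one
#'   column per condition; no missing values.
#' @return A list with `statistic` (Q), `p.value`, `n` (blocks) and `k`
#'   (conditions).
#' @export
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m)) stopf("blocks with missing values are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stopf("need at least 2 blocks and 2 conditions")
  R <- t(apply(m, 1, rank))
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  if (A == C) {
    return(list(statistic = 0, p.value = 1, n = n, k = k))
  }
  Rj <- colSums(R)
  Q <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  list(statistic = Q, p.value = pchisq(Q, k - 1, lower.tail = FALSE),
       n = n, k = k)
}

#' Friedman test per facial region
#'
#' Runs [friedman_test()] for each region across the three protocol states.
#' Blocks are subjects by default: each participant's frames are first
#' averaged within each phase (respecting the repeated-measures structure);
#' `blocks = "frame"` instead treats each frame index as a block, for
#' sensitivity checks.
#'
#' @inheritParams summarize_by_state
#' @param blocks `"subject"` (default) or `"frame"`.
#' @return A tibble with columns `roi`, `Q`, `p`, `n_blocks`, `k`,
#'   `p_lt_0.05`.
#' @export
friedman_by_roi <- function(features, blocks = c("subject", "frame")) {
  blocks <- match.arg(blocks)
  if (blocks == "subject") {
    data <- per_subject_phase_means(features)
    data$block <- data$participant_id
  } else {
    data <- features |>
      dplyr::group_by(.data$participant_id, .data$phase) |>
      dplyr::mutate(rep = dplyr::row_number()) |>
      dplyr::ungroup()
    data$block <- paste(data$participant_id, data$rep, sep = "/")
  }
  purrr::map_dfr(roi_names(), function(roi) {
    wide <- tidyr::pivot_wider(data[, c("block", "phase", roi)],
                               names_from = "phase",
                               values_from = dplyr::all_of(roi))
    m <- as.matrix(wide[, state_levels_ordered])
    res <- friedman_test(m)
    tibble(roi = roi, Q = res$statistic, p = res$p.value,
           n_blocks = res$n, k = res$k, p_lt_0.05 = res$p.value < 0.05)
  })
}

#' Export the state summary and Friedman results as one table
#'
#' Writes a CSV mirroring the per-region summary layout of the study
#' report: one row per region with mean/SD per state and the Friedman Q and
#' p, plus a `p_lt_0.05` significance column.
#'
#' @param summary Output of [summarize_by_state()].
#' @param friedman Output of [friedman_by_roi()].
#' @param path CSV path.
#' @return The wide tibble, invisibly.
#' @export
write_state_summary <- function(summary, friedman, path) {
  wide <- summary |>
    tidyr::pivot_wider(id_cols = "roi", names_from = "phase",
                       values_from = c("mean", "sd")) |>
    dplyr::left_join(
      dplyr::select(friedman, "roi", "p", "Q", "p_lt_0.05"),
      by = "roi")
  readr::write_csv(wide, path)
  invisible(wide)
}
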