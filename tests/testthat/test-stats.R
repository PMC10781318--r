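toy_features <- function(values_by_phase, n_subjects = 2) {
  # values_by_phase: named list phase -> vector of nose temps (recycled
  # across subjects); other regions held constant
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (phase in names(values_by_phase)) {
      vals <- values_by_phase[[phase]]
      for (i in seq_along(vals)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant_id = sprintf("P%02d", s),
          frame_id = sprintf("P%02d_%s_%d", s, phase, i),
          phase = phase, nose = vals[i], right_cheek = 35,
          left_cheek = 34.4, forehead = 35.5, chin = 34.6)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("state summaries use sample mean and n-1 SD", {
  feats <- toy_features(list(baseline = c(33, 35), stress = c(33, 35),
                             relax = c(33, 35)), n_subjects = 1)
  s <- summarize_by_state(feats)
  nose_base <- s[s$roi == "nose" & s$phase == "baseline", ]
  expect_equal(nose_base$mean, 34)
  expect_equal(nose_base$sd, sqrt(2))
  expect_equal(nose_base$n, 2L)

  # identical rows give SD 0 everywhere
  const <- toy_features(list(baseline = c(34, 34), stress = c(34, 34),
                             relax = c(34, 34)))
  expect_true(all(summarize_by_state(const)$sd == 0))

  # row order is irrelevant
  shuffled <- feats[rev(seq_len(nrow(feats))), ]
  expect_equal(summarize_by_state(shuffled), s)
})

test_that("per-subject phase means average each subject's frames", {
  feats <- toy_features(list(baseline = c(33, 33, 34, 34),
                             stress = c(33, 33, 34, 34),
                             relax = c(33, 33, 34, 34)))
  m <- per_subject_phase_means(feats)
  expect_true(all(m$nose == 33.5))
  expect_equal(nrow(m), 2 * 3)

  # matches a brute-force group-by on a randomized table
  config <- synth_config(n_subjects = 5, frames_per_phase = 3, seed = 5)
  table <- generate_feature_table(config)
  got <- per_subject_phase_means(table)
  for (row in sample(nrow(got), 10)) {
    sub <- table[table$participant_id == got$participant_id[row] &
                   table$phase == got$phase[row], ]
    expect_equal(got$nose[row], mean(sub$nose))
    expect_equal(got$chin[row], mean(sub$chin))
  }

  unbalanced <- feats[-1, ]
  expect_error(per_subject_phase_means(unbalanced), "unbalanced")
  expect_silent(per_subject_phase_means(unbalanced, allow_unbalanced = TRUE))
})

test_that("friedman_test matches hand results and the base-R cross-check", {
  # all blocks fully tied: no evidence, Q = 0, p = 1
  tied <- matrix(5, 6, 3)
  res <- friedman_test(tied)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  # strictly ordered rows: every block ranks 1 < 2 < 3
  ordered <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  res2 <- friedman_test(ordered)
  expect_equal(res2$statistic, 8)
  expect_equal(res2$p.value, pchisq(8, 2, lower.tail = FALSE))
  expect_equal(res2$statistic, oracle_friedman_q(ordered))

  # agrees with stats::friedman.test on random data, with and without ties
  withr::with_seed(31, {
    for (rep in 1:20) {
      m <- matrix(rnorm(45), 15, 3)
      if (rep > 10) m[sample(45, 5)] <- round(m[sample(45, 5)])
      mine <- friedman_test(m)
      base <- stats::friedman.test(m)
      expect_equal(mine$statistic, unname(base$statistic))
      expect_equal(mine$p.value, base$p.value)
    }
  })

  expect_error(friedman_test(matrix(c(1, NA, 3, 4, 5, 6), 2, 3)), "missing")
})

test_that("friedman_test depends only on within-block ranks", {
  withr::with_seed(32, {
    m <- matrix(rnorm(36), 12, 3)
  })
  res <- friedman_test(m)
  # strictly monotone transform of whole blocks leaves Q unchanged
  res2 <- friedman_test(exp(2 * m))
  expect_equal(res2$statistic, res$statistic)
})

test_that("per-region Friedman flows subject-level blocks through the test", {
  config <- synth_config(n_subjects = 8, frames_per_phase = 2, seed = 6)
  table <- generate_feature_table(config)
  out <- friedman_by_roi(table)
  expect_equal(nrow(out), 5L)
  expect_true(all(out$n_blocks == 8))
  expect_true(all(out$k == 3))
  expect_true(all(out$Q >= 0))
  expect_true(all(out$p > 0 & out$p <= 1))
  # manual check for one region
  blocks <- per_subject_phase_means(table)
  m <- tidyr::pivot_wider(blocks[, c("participant_id", "phase", "nose")],
                          names_from = "phase", values_from = "nose")
  manual <- friedman_test(as.matrix(m[, c("baseline", "stress", "relax")]))
  expect_equal(out$Q[out$roi == "nose"], manual$statistic)

  # frame-level blocks for sensitivity: more blocks, same structure
  out_frames <- friedman_by_roi(table, blocks = "frame")
  expect_true(all(out_frames$n_blocks == 16))
})

test_that("summary and Friedman results export in one wide table", {
  config <- synth_config(n_subjects = 4, frames_per_phase = 2, seed = 7)
  table <- generate_feature_table(config)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "summary.csv")
  wide <- write_state_summary(summarize_by_state(table),
                              friedman_by_roi(table), path)
  expect_true(file.exists(path))
  expect_equal(nrow(wide), 5L)
  expect_true(all(c("mean_baseline", "sd_stress", "p", "Q", "p_lt_0.05")
                  %in% names(wide)))
})
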