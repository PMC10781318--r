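# Shared fixtures and independent oracles. Oracles are written from the
# definitions directly (double loops, tallies, rank sums) and never call the
# implementation paths they check.

# small synthetic config that fits a 120x160 image, for fast tests
tiny_config <- function(...) {
  defaults <- list(n_subjects = 4, frames_per_phase = 2,
                   image_shape = c(120L, 160L),
                   box = face_box(30, 10, 80, 100), seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

round_away <- function(x) trunc(x + sign(x) * 0.5)

# Brute-force region membership: enumerate the pixel set of each region's
# summation index ranges, written out term by term.
oracle_region_pixels <- function(roi, ax, ay, w, h) {
  bounds <- switch(roi,
    nose = list(i = c(ax - round_away(w / 16), ax + round_away(w / 16)),
                j = c(ay - round_away(h / 13), ay)),
    right_cheek = list(i = c(ax - round_away(w / 3), ax - round_away(w / 5)),
                       j = c(ay - round_away(h / 14), ay + round_away(h / 14))),
    left_cheek = list(i = c(ax + round_away(w / 5), ax + round_away(12 * w / 35)),
                      j = c(ay - round_away(h / 14), ay + round_away(h / 14))),
    forehead = list(i = c(ax - round_away(w / 12), ax + round_away(w / 12)),
                    j = c(ay - round_away(h / 4), ay - round_away(h / 9))),
    chin = list(i = c(ax - round_away(w / 12), ax + round_away(w / 12)),
                j = c(ay - round_away(h / 8), ay))
  )
  pts <- expand.grid(i = bounds$i[1]:bounds$i[2], j = bounds$j[1]:bounds$j[2])
  pts[order(pts$i, pts$j), ]
}

region_pixels <- function(region) {
  pts <- expand.grid(i = region$i_lo:region$i_hi, j = region$j_lo:region$j_hi)
  pts[order(pts$i, pts$j), ]
}

# tally-based classification metrics oracle
oracle_report <- function(truth, pred) {
  levels <- c("baseline", "relax", "stress")
  out <- list()
  for (cls in levels) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    p <- 100 * tp / (tp + fp)
    r <- 100 * tp / (tp + fn)
    out[[cls]] <- c(precision = p, recall = r, f1 = 2 * p * r / (p + r))
  }
  out$accuracy <- 100 * mean(truth == pred)
  out
}

# rank-sum Friedman oracle (no tie correction; use on tie-free data only)
oracle_friedman_q <- function(m) {
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
}
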