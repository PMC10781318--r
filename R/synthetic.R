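#' Reference per-region state temperature distributions
#'
#' The per-region, per-state mean and SD (degrees Celsius) of facial skin
#' temperature observed across a short stress-induction protocol, used as
#' the anchor distributions for the synthetic generator: nose temperatures
#' drop under stress, cheeks and chin shift by a few tenths of a degree,
#' and spreads range from ~0.2 (forehead at rest) to ~1.3 (nose).
#'
#' @return A tibble with columns `roi`, `phase`, `mean`, `sd`.
#' @export
table1_reference <- function() {
  tibble(
    roi = rep(roi_names(), each = 3),
    phase = rep(c("baseline", "stress", "relax"), times = 5),
    mean = c(33.50, 33.28, 33.30,
             35.09, 34.90, 35.00,
             34.48, 34.32, 33.81,
             35.60, 35.42, 35.57,
             34.65, 34.68, 34.56),
    sd = c(1.22, 1.31, 1.23,
           0.51, 0.61, 0.57,
           0.72, 0.73, 1.17,
           0.18, 0.76, 0.18,
           0.44, 0.52, 0.33)
  )
}

ref_mu_matrix <- function() {
  ref <- table1_reference()
  m <- matrix(ref$mean, nrow = 5, byrow = TRUE,
              dimnames = list(roi_names(), c("baseline", "stress", "relax")))
  m
}

ref_sd_total <- function() {
  ref <- table1_reference()
  tapply(ref$sd, factor(ref$roi, roi_names()), mean)
}

#' Synthetic session configuration
#'
#' Describes a simulated acquisition session: `n_subjects` participants
#' each contribute `frames_per_phase` frames in each of the three states
#' (default 25 x 4 x 3 = 300 frames of 240 x 320 pixels, the protocol's
#' cardinality). Each region rectangle is stamped with
#' `grand_mean + state_effect_scale * (mu - grand_mean) + b + e`, where
#' `b` is a per-subject random offset shared across that subject's frames
#' and regions (SD `sd_total * sqrt(subject_sd_fraction)`, perfectly
#' correlated across regions via one standard-normal draw scaled by each
#' region's SD) and `e` is per-frame, per-region noise (SD
#' `sd_total * sqrt(1 - subject_sd_fraction)`), so each region's marginal
#' SD is `sd_total`. Pixel-level texture noise (SD `pixel_noise_sd`) is
#' added on top but excluded from the recorded ground truth.
#'
#' Two presets:
#' * `"table1"` — `state_effect_scale = 1`, `noise_scale = 1`: marginal
#'   means and SDs match the reference distributions; intended for
#'   summary-statistic recovery.
#' * `"separable"` — `state_effect_scale = 3`, `noise_scale = 1/3`: state
#'   contrasts amplified and noise shrunk so that a subject-held-out
#'   classifier reaches the ~95% accuracy regime; intended for
#'   classifier-recovery checks.
#'
#' @param preset `"table1"` or `"separable"`.
#' @param n_subjects,frames_per_phase Session cardinality.
#' @param image_shape Integer `(rows, cols)`, default 240 x 320.
#' @param t_min,t_max Config-level temperature clamp range (degrees
#'   Celsius); every stamped temperature must lie inside it. Each written
#'   frame's sidecar scale is the rendered field's own min/max (emulating
#'   auto-ranged thermal exports, which keeps per-frame-maximum decoding
#'   self-consistent).
#' @param max_gray Encoding gray ceiling (255 = 8-bit).
#' @param mu Optional 5x3 matrix of region x state means overriding the
#'   reference values.
#' @param sd_total Optional named length-5 vector of per-region marginal
#'   SDs; defaults to the mean of each region's three reference SDs.
#' @param subject_sd_fraction Share of `sd_total^2` assigned to the subject
#'   random effect, in `[0, 1]`.
#' @param state_effect_scale Multiplier on between-state mean deviations;
#'   default per preset.
#' @param noise_scale Multiplier on `sd_total`; default per preset.
#' @param background_temp,face_base_temp Scene temperatures outside /
#'   inside the elliptical face mask.
#' @param pixel_noise_sd Pixel texture SD (degrees Celsius).
#' @param box [face_box()] used for every frame (subjects face the camera
#'   throughout, so pose is fixed).
#' @param seed Integer seed; the session is fully determined by it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(preset = c("table1", "separable"),
                         n_subjects = 25, frames_per_phase = 4,
                         image_shape = c(240L, 320L),
                         t_min = 18, t_max = 40, max_gray = 255L,
                         mu = NULL, sd_total = NULL,
                         subject_sd_fraction = 0.5,
                         state_effect_scale = NULL,
                         noise_scale = NULL,
                         background_temp = 24, face_base_temp = 33,
                         pixel_noise_sd = 0.1,
                         box = face_box(90, 30, 140, 180),
                         seed = 1L) {
  preset <- match.arg(preset)
  state_effect_scale <- state_effect_scale %||%
    if (preset == "separable") 3 else 1
  noise_scale <- noise_scale %||% if (preset == "separable") 1 / 3 else 1
  mu <- mu %||% ref_mu_matrix()
  sd_total <- sd_total %||% (ref_sd_total() * noise_scale)
  stopifnot(all(sd_total >= 0), subject_sd_fraction >= 0,
            subject_sd_fraction <= 1, t_min < t_max)
  if (any(mu <= t_min) || any(mu >= t_max)) {
    stopf("state means must lie strictly inside the (%g, %g) scale",
          t_min, t_max, class = "thermoface_config_error")
  }
  structure(
    list(preset = preset, n_subjects = as.integer(n_subjects),
         frames_per_phase = as.integer(frames_per_phase),
         image_shape = as.integer(image_shape),
         t_min = t_min, t_max = t_max, max_gray = as.integer(max_gray),
         mu = mu, sd_total = sd_total,
         subject_sd_fraction = subject_sd_fraction,
         state_effect_scale = state_effect_scale,
         background_temp = background_temp,
         face_base_temp = face_base_temp,
         pixel_noise_sd = pixel_noise_sd,
         box = box, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Canonical 68-point landmark template
#'
#' A fixed frontal 68-point layout (jawline arc, brows, nose bridge and
#' base, eyes, mouth) in normalized face-box coordinates, scaled and
#' translated into a given box. The anchoring points land at their
#' anatomical positions: 9 at the chin bottom, 28 at the top of the nose
#' bridge, 31 at the nose base, 34 under the nose tip.
#'
#' @param box A [face_box()] at least 32 px on each side.
#' @param image_shape Integer `(rows, cols)` the points must fit in.
#' @return A [landmark_set()].
#' @export
canonical_landmark_template <- function(box, image_shape) {
  if (box$w < 32 || box$h < 32) {
    stopf("face box too small for the landmark template (min 32 px per side)",
          class = "thermoface_format_error")
  }
  deg <- pi / 180
  jaw_phi <- seq(-80, 80, length.out = 17) * deg
  u <- c(
    0.5 - 0.46 * sin(jaw_phi),                       # 1-17 jawline
    seq(0.15, 0.40, length.out = 5),                 # 18-22 brow
    seq(0.60, 0.85, length.out = 5),                 # 23-27 brow
    rep(0.5, 4),                                     # 28-31 nose bridge
    seq(0.42, 0.58, length.out = 5),                 # 32-36 nose base
    0.30 + 0.06 * cos(seq(180, -120, by = -60) * deg),  # 37-42 eye
    0.70 + 0.06 * cos(seq(180, -120, by = -60) * deg),  # 43-48 eye
    0.50 + 0.13 * cos(seq(180, -150, by = -30) * deg),  # 49-60 outer lips
    0.50 + 0.08 * cos(seq(180, -135, by = -45) * deg)   # 61-68 inner lips
  )
  v <- c(
    0.5 + 0.48 * cos(jaw_phi),
    rep(0.30, 10),
    seq(0.40, 0.58, length.out = 4),
    c(0.60, 0.615, 0.62, 0.615, 0.60),
    0.40 - 0.025 * sin(seq(180, -120, by = -60) * deg),
    0.40 - 0.025 * sin(seq(180, -120, by = -60) * deg),
    0.80 - 0.055 * sin(seq(180, -150, by = -30) * deg),
    0.80 - 0.030 * sin(seq(180, -135, by = -45) * deg)
  )
  landmark_set(cbind(x = box$x + u * box$w, y = box$y + v * box$h),
               image_shape = image_shape)
}

#' Draw a per-subject temperature offset
#'
#' One standard-normal draw per subject, scaled by each region's
#' `sd_total * sqrt(subject_sd_fraction)`; the offset is shared across all
#' of the subject's frames and regions, inducing the within-subject
#' correlation of a repeated-measures design.
#'
#' @param config A [synth_config()].
#' @return Named length-5 numeric vector of offsets (degrees Celsius).
#' @export
draw_subject_effect <- function(config) {
  z <- rnorm(1)
  config$sd_total * sqrt(config$subject_sd_fraction) * z
}

# stamped ground-truth region temperatures for one frame
stamp_values <- function(config, phase, subject_effect) {
  gm <- rowMeans(config$mu)
  eps <- rnorm(5, 0, config$sd_total * sqrt(1 - config$subject_sd_fraction))
  v <- gm + config$state_effect_scale * (config$mu[, phase] - gm) +
    subject_effect + eps
  if (any(v <= config$t_min) || any(v >= config$t_max)) {
    stopf("stamped temperature outside the (%g, %g) scale",
          config$t_min, config$t_max, class = "thermoface_config_error")
  }
  setNames(as.numeric(v), roi_names())
}

#' Render one synthetic thermal frame
#'
#' Builds the temperature field — background outside an elliptical face
#' mask, a base face temperature inside, each region rectangle stamped
#' with its ground-truth value, pixel texture noise on top — and encodes
#' it to gray levels with the frame's own min/max as the sidecar scale.
#'
#' @param config A [synth_config()].
#' @param subject_id,phase,rep_index Frame identity.
#' @param subject_effect Offset vector from [draw_subject_effect()].
#' @return A list with `frame` (a [thermal_frame()] carrying its landmarks
#'   and face box) and `truth` (one-row tibble of the stamped values,
#'   pre-quantization, excluding pixel texture).
#' @export
render_frame <- function(config, subject_id, phase, rep_index = 1L,
                         subject_effect = rep(0, 5)) {
  shape <- config$image_shape
  box <- config$box
  lm <- canonical_landmark_template(box, shape)
  stamped <- stamp_values(config, phase, subject_effect)

  rowv <- seq_len(shape[1]) - 1  # 0-based y
  colv <- seq_len(shape[2]) - 1  # 0-based x
  cx <- box$x + box$w / 2; cy <- box$y + box$h / 2
  dy2 <- ((rowv - cy) / (0.49 * box$h))^2
  dx2 <- ((colv - cx) / (0.48 * box$w))^2
  mask <- outer(dy2, dx2, `+`) <= 1
  field <- matrix(config$background_temp, shape[1], shape[2])
  field[mask] <- config$face_base_temp

  regions <- roi_regions(lm, box, shape)
  for (roi in roi_names()) {
    r <- regions[[roi]]
    field[(r$j_lo + 1):(r$j_hi + 1), (r$i_lo + 1):(r$i_hi + 1)] <- stamped[[roi]]
  }
  if (config$pixel_noise_sd > 0) {
    field <- field + matrix(rnorm(length(field), 0, config$pixel_noise_sd),
                            shape[1], shape[2])
    field <- pmin(pmax(field, config$t_min), config$t_max)
  }
  frame_id <- sprintf("%s_%s_%d", subject_id, phase, rep_index)
  frame <- encode_frame(field, min(field), max(field),
                        max_gray = config$max_gray,
                        frame_id = frame_id, participant_id = subject_id,
                        phase = phase)
  frame$face_box <- box
  frame$landmarks <- lm
  truth <- tibble(participant_id = subject_id, frame_id = frame_id,
                  phase = phase, !!!as.list(stamped))
  list(frame = frame, truth = truth)
}

#' Generate a full synthetic session
#'
#' Renders `n_subjects x 3 phases x frames_per_phase` frames (default 300),
#' each with ground-truth landmarks, face box, and stamped region
#' temperatures. Fully determined by `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `frames` (list of [thermal_frame()]), `truth`
#'   (feature tibble of stamped values, one row per frame) and `config`.
#' @export
generate_session <- function(config = synth_config()) {
  phases <- c("baseline", "stress", "relax")
  withr::with_seed(config$seed, {
    frames <- list(); truth <- list()
    for (s in seq_len(config$n_subjects)) {
      subject_id <- sprintf("P%02d", s)
      b <- draw_subject_effect(config)
      for (phase in phases) {
        for (r in seq_len(config$frames_per_phase)) {
          res <- render_frame(config, subject_id, phase, r, b)
          frames[[length(frames) + 1L]] <- res$frame
          truth[[length(truth) + 1L]] <- res$truth
        }
      }
    }
    list(frames = frames, truth = dplyr::bind_rows(truth), config = config)
  })
}

#' Generate only the ground-truth feature table
#'
#' Draws the stamped region temperatures of [generate_session()] without
#' rendering pixels — the same statistical model at a fraction of the
#' cost, for classifier and summary studies that do not need images.
#' Note the draw sequence differs from [generate_session()] (no pixel
#' noise is consumed), so the two are separate random experiments even at
#' the same seed.
#'
#' @param config A [synth_config()].
#' @return A feature tibble (one row per frame).
#' @export
generate_feature_table <- function(config = synth_config()) {
  phases <- c("baseline", "stress", "relax")
  withr::with_seed(config$seed, {
    rows <- list()
    for (s in seq_len(config$n_subjects)) {
      subject_id <- sprintf("P%02d", s)
      b <- draw_subject_effect(config)
      for (phase in phases) {
        for (r in seq_len(config$frames_per_phase)) {
          stamped <- stamp_values(config, phase, b)
          rows[[length(rows) + 1L]] <- tibble(
            participant_id = subject_id,
            frame_id = sprintf("%s_%s_%d", subject_id, phase, r),
            phase = phase, !!!as.list(stamped))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a synthetic session to disk
#'
#' Emits, per frame, the grayscale image (PNG for 8-bit, TIFF otherwise),
#' the JSON sidecar with scale, identifiers and face box, and the
#' ground-truth landmark CSV; plus a `manifest.csv` listing all frames and
#' a `truth_features.csv` of the stamped region temperatures.
#'
#' @param session Output of [generate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (session$config$max_gray > 255L) "tif" else "png"
  manifest <- purrr::map_dfr(session$frames, function(fr) {
    img <- file.path(dir, paste0(fr$frame_id, ".", ext))
    write_thermal_frame(fr, img)
    tibble(frame_id = fr$frame_id, participant_id = fr$participant_id,
           phase = fr$phase, image = basename(img),
           sidecar = basename(sidecar_path_for(img)),
           landmarks = basename(landmark_path_for(img)))
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  write_features(session$truth, file.path(dir, "truth_features.csv"))
  invisible(dir)
}
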