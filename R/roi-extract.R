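#' Mean temperature over a pixel region
#'
#' Arithmetic mean over every pixel in the inclusive rectangle. Because the
#' gray-to-temperature decoding is affine, averaging decoded temperatures
#' is equivalent to decoding the mean gray value; the package averages
#' temperatures, matching how the feature database is built.
#'
#' @param temps Temperature matrix from [decode_frame()].
#' @param region A [roi_region()].
#' @return A list with `mean` (degrees Celsius) and `n_pixels`.
#' @export
roi_mean_temperature <- function(temps, region) {
  stopifnot(inherits(region, "pixel_region"))
  rows <- (region$j_lo + 1):(region$j_hi + 1)
  cols <- (region$i_lo + 1):(region$i_hi + 1)
  if (max(rows) > nrow(temps) || max(cols) > ncol(temps)) {
    stopf("region exceeds the temperature matrix",
          class = "thermoface_empty_region")
  }
  block <- temps[rows, cols, drop = FALSE]
  list(mean = mean(block), n_pixels = length(block))
}

#' Extract the five ROI mean temperatures from one frame
#'
#' Decodes the frame once, builds the five pixel regions from the landmark
#' anchors and face box, and averages the temperature inside each.
#'
#' @param frame A [thermal_frame()].
#' @param landmarks,box Optional explicit [landmark_set()] / [face_box()];
#'   when omitted, `provider` locates them.
#' @param provider A [landmark_provider()] used when landmarks/box are not
#'   given.
#' @param t_mgv_mode Passed to [decode_frame()].
#' @return A tibble with one row per region: `frame_id`, `participant_id`,
#'   `phase`, `roi`, `mean_temp`, `n_pixels`, `clipped`.
#' @export
extract_rois <- function(frame, landmarks = NULL, box = NULL,
                         provider = landmark_provider(),
                         t_mgv_mode = "frame") {
  if (is.null(landmarks) || is.null(box)) {
    det <- detect_landmarks(frame, provider)
    landmarks <- landmarks %||% det$landmarks
    box <- box %||% det$box
  }
  temps <- decode_frame(frame, t_mgv_mode = t_mgv_mode)
  regions <- roi_regions(landmarks, box, dim(frame$pixels))
  purrr::imap_dfr(regions, function(region, roi) {
    m <- roi_mean_temperature(temps, region)
    tibble(frame_id = frame$frame_id,
           participant_id = frame$participant_id,
           phase = frame$phase,
           roi = roi,
           mean_temp = m$mean,
           n_pixels = m$n_pixels,
           clipped = region$clipped)
  })
}

#' Build a wide feature table from many frames
#'
#' Runs [extract_rois()] over a list of frames (or a directory of
#' image + sidecar pairs) and pivots to the classifier's input layout: one
#' row per frame with the five region temperatures as columns. Frames where
#' landmark detection or region construction fails are skipped with a
#' warning and counted in the `n_failed` attribute.
#'
#' @param frames A list of [thermal_frame()] objects, or a directory path
#'   containing `.png`/`.tif` frames with sidecars.
#' @inheritParams extract_rois
#' @return A tibble with columns `participant_id`, `frame_id`, `phase`,
#'   `nose`, `right_cheek`, `left_cheek`, `forehead`, `chin` (degrees
#'   Celsius), with attribute `n_failed`.
#' @export
extract_features <- function(frames, provider = landmark_provider(),
                             t_mgv_mode = "frame") {
  if (is.character(frames) && length(frames) == 1L) {
    paths <- sort(list.files(frames, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    frames <- lapply(paths, read_thermal_frame)
  }
  n_failed <- 0L
  rows <- purrr::map(frames, function(fr) {
    tryCatch(
      extract_rois(fr, provider = provider, t_mgv_mode = t_mgv_mode),
      error = function(e) {
        warn(sprintf("skipping frame '%s': %s", fr$frame_id,
                     conditionMessage(e)))
        n_failed <<- n_failed + 1L
        NULL
      })
  })
  long <- dplyr::bind_rows(rows)
  if (nrow(long) == 0L) {
    stopf("no frame could be processed", class = "thermoface_detection_error")
  }
  wide <- tidyr::pivot_wider(long,
                             id_cols = c("participant_id", "frame_id", "phase"),
                             names_from = "roi", values_from = "mean_temp")
  wide <- dplyr::select(wide, "participant_id", "frame_id", "phase",
                        dplyr::all_of(roi_names()))
  attr(wide, "n_failed") <- n_failed
  wide
}

#' Read / write feature tables
#'
#' The feature CSV holds one row per frame with the five region mean
#' temperatures; temperatures are formatted to 2 decimals on write.
#'
#' @param features A feature tibble from [extract_features()].
#' @param path CSV path.
#' @return `read_features()` returns the feature tibble;
#'   `write_features()` returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  out <- dplyr::mutate(features,
                       dplyr::across(dplyr::all_of(roi_names()),
                                     ~ sprintf("%.2f", .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    frame_id = readr::col_character(),
    phase = readr::col_character(),
    .default = readr::col_double()))
}
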