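# Landmark indices (1-based, standard 68-point numbering) anchoring the five
# facial regions: 9 = chin bottom, 28 = nose bridge top, 31 = nose base
# (anchors both cheeks), 34 = point under the nose tip.
anchor_indices <- c(chin = 9L, forehead = 28L, cheeks = 31L, nose = 34L)

#' Construct a 68-point facial landmark set
#'
#' Pixel coordinates are 0-based with `x` increasing rightward (columns) and
#' `y` increasing downward (rows), matching image conventions; the 1-based
#' point numbering of the standard 68-point annotation is kept at the
#' interface (so "landmark 34" means row 34 of `points`).
#'
#' @param points A 68-row numeric matrix or data frame with columns `x`, `y`
#'   (real-valued pixel coordinates).
#' @param image_shape Integer `(rows, cols)` of the image the points live in.
#' @return An object of class `landmark_set`: a tibble with columns
#'   `index`, `x`, `y` and an `image_shape` attribute.
#' @export
landmark_set <- function(points, image_shape) {
  points <- as.data.frame(points)
  if (ncol(points) == 3L && "index" %in% names(points)) {
    points <- points[order(points$index), c("x", "y")]
  }
  colnames(points) <- c("x", "y")
  if (nrow(points) != 68L) {
    stopf("a landmark set requires exactly 68 points, got %d", nrow(points),
          class = "thermoface_format_error")
  }
  rows <- image_shape[1]; cols <- image_shape[2]
  if (any(points$x < 0) || any(points$x > cols - 1) ||
      any(points$y < 0) || any(points$y > rows - 1)) {
    stopf("landmark coordinates fall outside the %dx%d image", rows, cols,
          class = "thermoface_format_error")
  }
  out <- tibble(index = 1:68, x = as.numeric(points$x), y = as.numeric(points$y))
  attr(out, "image_shape") <- as.integer(image_shape)
  class(out) <- c("landmark_set", class(out))
  out
}

#' Construct a detected-face box
#'
#' `x`, `y` is the top-left pixel (0-based); `w` and `h` are the width and
#' height in pixels of the detected face. The five region equations scale
#' with this box.
#'
#' @param x,y Top-left pixel coordinates.
#' @param w,h Width and height in pixels (positive).
#' @return An object of class `face_box`.
#' @export
face_box <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) {
    stopf("face box must have positive width and height",
          class = "thermoface_format_error")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "face_box")
}

#' Derive a face box from landmark extremes
#'
#' Fallback when no detector/sidecar box is available: the tight bounding
#' box of the 68 points. Note the region equations are calibrated against a
#' detected-face box, not the landmark hull, so this box is a labelled
#' approximation (the landmark hull excludes the forehead above the brows).
#'
#' @param lm A [landmark_set()].
#' @return A [face_box()].
#' @export
face_box_from_landmarks <- function(lm) {
  face_box(min(lm$x), min(lm$y),
           max(lm$x) - min(lm$x), max(lm$y) - min(lm$y))
}

#' Read / write landmark CSV files
#'
#' The interchange format is a CSV with columns `index,x,y`, one row per
#' landmark, `index` running 1..68; coordinates are preserved as reals.
#'
#' @param path CSV path.
#' @param image_shape Integer `(rows, cols)`; required on read so bounds can
#'   be validated.
#' @return `read_landmarks()` returns a [landmark_set()];
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path, image_shape) {
  df <- readr::read_csv(path, col_types = readr::cols(
    index = readr::col_integer(),
    x = readr::col_double(),
    y = readr::col_double()))
  if (nrow(df) != 68L || anyDuplicated(df$index) ||
      !setequal(df$index, 1:68)) {
    stopf("'%s' is not a valid 68-point landmark file", path,
          class = "thermoface_format_error")
  }
  landmark_set(df, image_shape = image_shape)
}

#' @rdname read_landmarks
#' @param lm A [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  readr::write_csv(tibble(index = lm$index, x = lm$x, y = lm$y), path)
  invisible(path)
}

#' Landmark providers
#'
#' A provider locates the 68 landmarks and the face box for a frame, behind
#' one contract so downstream code never sees partial sets:
#'
#' * `"sidecar"` (default) returns the ground-truth landmark set and face
#'   box carried by the frame (attached by [read_thermal_frame()] or the
#'   synthetic generator). Localization-sensitive analyses should use this.
#' * `"template"` is a simple self-contained detector for frontal synthetic
#'   faces: it thresholds the temperature field midway between the coldest
#'   and warmest pixels, takes the bounding box of the warm (face) region,
#'   and fits the canonical 68-point template into it. It is a
#'   threshold-plus-template fit, not a trained appearance model.
#'
#' @param backend `"sidecar"` or `"template"`.
#' @return A `landmark_provider` object for [detect_landmarks()].
#' @export
landmark_provider <- function(backend = c("sidecar", "template")) {
  backend <- match.arg(backend)
  structure(list(backend = backend), class = "landmark_provider")
}

#' Locate landmarks and a face box in a frame
#'
#' @param frame A [thermal_frame()].
#' @param provider A [landmark_provider()].
#' @return A list with elements `landmarks` ([landmark_set()]) and
#'   `box` ([face_box()]).
#' @export
detect_landmarks <- function(frame, provider = landmark_provider()) {
  stopifnot(inherits(frame, "thermal_frame"),
            inherits(provider, "landmark_provider"))
  if (provider$backend == "sidecar") {
    if (is.null(frame$landmarks) || is.null(frame$face_box)) {
      stopf("frame '%s' carries no sidecar landmarks/face box",
            frame$frame_id, class = "thermoface_detection_error")
    }
    return(list(landmarks = frame$landmarks, box = frame$face_box))
  }
  temps <- decode_frame(frame)
  thr <- (min(temps) + max(temps)) / 2
  mask <- temps > thr
  if (!any(mask)) {
    stopf("no face found in frame '%s'", frame$frame_id,
          class = "thermoface_detection_error")
  }
  ij <- which(mask, arr.ind = TRUE)
  # bounding box of the warm region, 0-based pixel coordinates
  x0 <- min(ij[, 2]) - 1; x1 <- max(ij[, 2]) - 1
  y0 <- min(ij[, 1]) - 1; y1 <- max(ij[, 1]) - 1
  box <- face_box(x0, y0, x1 - x0, y1 - y0)
  list(landmarks = canonical_landmark_template(box, dim(frame$pixels)),
       box = box)
}
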