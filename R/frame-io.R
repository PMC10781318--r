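sidecar_path_for <- function(path) {
  paste0(sub("\\.(png|tif|tiff)$", "", path, ignore.case = TRUE), ".json")
}

landmark_path_for <- function(path) {
  paste0(sub("\\.(png|tif|tiff)$", "", path, ignore.case = TRUE),
         "_landmarks.csv")
}

#' Write a thermal frame and its metadata sidecar
#'
#' Pixels go to an 8-bit grayscale PNG or an 8/16-bit grayscale TIFF
#' (chosen by file extension); the temperature scale and identifiers go to a
#' JSON sidecar next to the image. If the frame carries a face box it is
#' written into the sidecar; if it carries landmarks they are written to a
#' `<stem>_landmarks.csv` via [write_landmarks()]. The round trip through
#' [read_thermal_frame()] is lossless.
#'
#' @param frame A [thermal_frame()].
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @param sidecar_path JSON sidecar path; defaults to the image path with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_thermal_frame <- function(frame, path, sidecar_path = NULL) {
  stopifnot(inherits(frame, "thermal_frame"))
  sidecar_path <- sidecar_path %||% sidecar_path_for(path)
  max_gray <- frame$max_gray %||% if (frame$t_mgv > 255L) 65535L else 255L
  ext <- tolower(sub(".*\\.", "", path))
  img <- frame$pixels / max_gray
  if (ext == "png") {
    if (max_gray > 255L) {
      stopf("PNG output supports 8-bit frames only; use TIFF for 16-bit")
    }
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path,
                    bits.per.sample = if (max_gray > 255L) 16L else 8L)
  } else {
    stopf("unsupported image extension '.%s'", ext,
          class = "thermoface_format_error")
  }
  meta <- list(t_min = frame$t_min, t_max = frame$t_max,
               max_gray = max_gray,
               frame_id = frame$frame_id,
               participant_id = frame$participant_id,
               phase = frame$phase)
  if (!is.null(frame$face_box)) {
    meta$face_box <- unclass(frame$face_box)[c("x", "y", "w", "h")]
  }
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!is.null(frame$landmarks)) {
    write_landmarks(frame$landmarks, landmark_path_for(path))
  }
  invisible(path)
}

#' Read a thermal frame and its metadata sidecar
#'
#' @param path Grayscale PNG or TIFF path.
#' @param sidecar_path JSON sidecar path; defaults to the image path with a
#'   `.json` extension. Must supply `t_min` and `t_max`.
#' @return A [thermal_frame()]; if a `<stem>_landmarks.csv` exists next to
#'   the image, the landmark set (and any sidecar face box) is attached.
#' @export
read_thermal_frame <- function(path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% sidecar_path_for(path)
  if (!file.exists(sidecar_path)) {
    stopf("missing sidecar '%s'", sidecar_path,
          class = "thermoface_format_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("t_min", "t_max")) {
    if (is.null(meta[[key]])) {
      stopf("sidecar '%s' lacks required key '%s'", sidecar_path, key,
            class = "thermoface_format_error")
    }
  }
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stopf("unsupported image extension '.%s'", ext,
          class = "thermoface_format_error")
  }
  if (length(dim(img)) != 2L) {
    stopf("'%s' is not single-channel grayscale", path,
          class = "thermoface_format_error")
  }
  max_gray <- as.integer(meta$max_gray %||% 255L)
  pixels <- matrix(as.integer(round(img * max_gray)), nrow = nrow(img))
  box <- if (!is.null(meta$face_box)) {
    face_box(meta$face_box$x, meta$face_box$y,
             meta$face_box$w, meta$face_box$h)
  }
  lm_path <- landmark_path_for(path)
  lms <- if (file.exists(lm_path)) {
    read_landmarks(lm_path, image_shape = dim(pixels))
  }
  thermal_frame(pixels, meta$t_min, meta$t_max,
                frame_id = meta$frame_id %||% basename(path),
                participant_id = meta$participant_id %||% NA_character_,
                phase = meta$phase %||% NA_character_,
                max_gray = max_gray, face_box = box, landmarks = lms)
}
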