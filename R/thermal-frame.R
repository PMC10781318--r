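#' Construct a thermal frame
#'
#' A thermal frame couples a stored grayscale pixel matrix with the
#' temperature scale needed to decode it: the scale endpoints `t_min` and
#' `t_max` (degrees Celsius) and the frame's largest gray value `t_mgv`,
#' which is derived from the pixels and acts as the decoding denominator.
#'
#' @param pixels Integer matrix of gray values, origin top-left (row 1 is the
#'   top image row). Values must be non-negative and, if `max_gray` is given,
#'   must not exceed it.
#' @param t_min,t_max Temperature scale endpoints in degrees Celsius;
#'   `t_min < t_max` is required.
#' @param frame_id,participant_id Identifier strings.
#' @param phase Protocol phase label: one of `"baseline"`, `"stress"`,
#'   `"relax"`, `"acclimatization"` or `NA` when unknown.
#' @param max_gray Optional storage bit-depth ceiling (255 for 8-bit,
#'   65535 for 16-bit). Used for validation and by `decode_frame()`'s
#'   `"full_scale"` mode.
#' @param face_box Optional [face_box()] carried from a sidecar.
#' @param landmarks Optional [landmark_set()] carried from a sidecar.
#'
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(pixels, t_min, t_max,
                          frame_id = "frame", participant_id = NA_character_,
                          phase = NA_character_, max_gray = NULL,
                          face_box = NULL, landmarks = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("`pixels` must be a numeric matrix", class = "thermoface_invalid_frame")
  }
  if (any(pixels != floor(pixels)) || any(pixels < 0)) {
    stopf("gray values must be non-negative integers",
          class = "thermoface_invalid_frame")
  }
  if (!is_scalar_number(t_min) || !is_scalar_number(t_max) || t_min >= t_max) {
    stopf("temperature scale requires t_min < t_max",
          class = "thermoface_invalid_frame")
  }
  t_mgv <- max(pixels)
  if (t_mgv == 0) {
    stopf("all-zero frame: the largest gray value must be positive",
          class = "thermoface_invalid_frame")
  }
  if (!is.null(max_gray) && t_mgv > max_gray) {
    stopf("gray values exceed the declared bit depth (%d > %d)",
          t_mgv, max_gray, class = "thermoface_invalid_frame")
  }
  phase <- as.character(phase)
  known <- c("baseline", "stress", "relax", "acclimatization")
  if (!is.na(phase) && !phase %in% known) {
    stopf("unknown phase '%s'", phase, class = "thermoface_invalid_frame")
  }
  structure(
    list(pixels = pixels, t_min = t_min, t_max = t_max,
         t_mgv = as.integer(t_mgv),
         max_gray = if (is.null(max_gray)) NULL else as.integer(max_gray),
         frame_id = frame_id, participant_id = participant_id, phase = phase,
         face_box = face_box, landmarks = landmarks),
    class = "thermal_frame"
  )
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf(
    "<thermal_frame> %s  %dx%d px  scale [%.2f, %.2f] degC  t_mgv=%d  phase=%s\n",
    x$frame_id, nrow(x$pixels), ncol(x$pixels),
    x$t_min, x$t_max, x$t_mgv, x$phase))
  invisible(x)
}

#' Decode gray values to temperature
#'
#' Converts stored gray levels to temperature on the frame's scale:
#' `t_min + gray / t_mgv * (t_max - t_min)`. A gray value of 0 maps to
#' `t_min` and the frame's largest gray value `t_mgv` maps to `t_max`.
#'
#' @param gray Integer vector of gray values in `[0, t_mgv]`.
#' @param t_min,t_max Temperature scale endpoints (degrees Celsius).
#' @param t_mgv Largest gray value in the frame (decoding denominator),
#'   at least 1.
#' @return Numeric vector of temperatures in degrees Celsius.
#' @export
#' @examples
#' decode_pixel(128, 30, 38, 255)
decode_pixel <- function(gray, t_min, t_max, t_mgv) {
  if (!is_scalar_number(t_mgv) || t_mgv < 1) {
    stopf("t_mgv must be a positive integer (all-zero frames cannot be decoded)",
          class = "thermoface_invalid_frame")
  }
  if (any(gray < 0) || any(gray > t_mgv)) {
    stopf("gray value outside [0, t_mgv = %d]", t_mgv,
          class = "thermoface_out_of_range")
  }
  if (t_min >= t_max) {
    stopf("temperature scale requires t_min < t_max",
          class = "thermoface_invalid_frame")
  }
  t_min + (gray / t_mgv) * (t_max - t_min)
}

#' Decode a whole frame to a temperature matrix
#'
#' Applies [decode_pixel()] elementwise. By default the denominator is the
#' frame's own largest gray value (`t_mgv`), which assumes the hottest pixel
#' sits at `t_max` — the convention of auto-ranged thermal exports. For
#' cameras that write full-scale maps (hottest pixel not necessarily at the
#' scale top), `t_mgv_mode = "full_scale"` uses the declared bit-depth
#' maximum instead.
#'
#' @param frame A [thermal_frame()].
#' @param t_mgv_mode `"frame"` (default) or `"full_scale"`.
#' @return Numeric temperature matrix (degrees Celsius) with the same shape
#'   as `frame$pixels` and attributes `t_min`/`t_max`.
#' @export
decode_frame <- function(frame, t_mgv_mode = c("frame", "full_scale")) {
  stopifnot(inherits(frame, "thermal_frame"))
  t_mgv_mode <- match.arg(t_mgv_mode)
  denom <- if (t_mgv_mode == "frame") {
    frame$t_mgv
  } else {
    if (is.null(frame$max_gray)) {
      stopf("full_scale decoding requires a declared max_gray",
            class = "thermoface_invalid_frame")
    }
    frame$max_gray
  }
  out <- decode_pixel(frame$pixels, frame$t_min, frame$t_max, denom)
  attr(out, "t_min") <- frame$t_min
  attr(out, "t_max") <- frame$t_max
  out
}

#' Encode a temperature matrix as a grayscale frame
#'
#' Inverse of [decode_frame()] for fixture generation: maps each temperature
#' linearly onto `[0, max_gray]` and rounds half away from zero. The emitted
#' frame's `t_mgv` is recomputed from the pixels (no pixel is forced to
#' `max_gray`), so exact decode round-trips hold only when some value sits
#' at `t_max`.
#'
#' @param values Numeric temperature matrix, all values in `[t_min, t_max]`.
#' @param t_min,t_max Scale endpoints (degrees Celsius).
#' @param max_gray Gray ceiling (default 255).
#' @inheritParams thermal_frame
#' @return A [thermal_frame()].
#' @export
encode_frame <- function(values, t_min, t_max, max_gray = 255L,
                         frame_id = "frame", participant_id = NA_character_,
                         phase = NA_character_) {
  if (!is.matrix(values)) stopf("`values` must be a matrix")
  if (any(values < t_min) || any(values > t_max)) {
    stopf("temperature outside scale [%.3f, %.3f]", t_min, t_max,
          class = "thermoface_out_of_range")
  }
  if (max_gray < 1) stopf("max_gray must be >= 1")
  gray <- round_half_out((values - t_min) / (t_max - t_min) * max_gray)
  gray <- matrix(as.integer(gray), nrow = nrow(values))
  thermal_frame(gray, t_min, t_max, frame_id = frame_id,
                participant_id = participant_id, phase = phase,
                max_gray = as.integer(max_gray))
}

#' Temperature increment represented by one gray level
#'
#' @param frame A [thermal_frame()].
#' @return `(t_max - t_min) / t_mgv` in degrees Celsius.
#' @export
quantization_step <- function(frame) {
  (frame$t_max - frame$t_min) / frame$t_mgv
}
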