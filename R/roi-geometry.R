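#' The five facial regions of interest
#'
#' @return Character vector `c("nose", "right_cheek", "left_cheek",
#'   "forehead", "chin")`, the fixed region order used throughout.
#' @export
roi_names <- function() {
  c("nose", "right_cheek", "left_cheek", "forehead", "chin")
}

# Region bounds as fractions of the face-box width (dx, applied to the
# anchor x) and height (dy, applied to the anchor y). Inclusive on both
# ends. "right cheek" is the region at lower column indices (image left),
# exactly as the selection equations are written; no anatomical mirroring
# is applied.
roi_offset_fractions <- function() {
  tibble(
    roi   = roi_names(),
    dx_lo = c(-1 / 16, -1 / 3,  1 / 5,  -1 / 12, -1 / 12),
    dx_hi = c( 1 / 16, -1 / 5,  12 / 35, 1 / 12,  1 / 12),
    dy_lo = c(-1 / 13, -1 / 14, -1 / 14, -1 / 4,  -1 / 8),
    dy_hi = c( 0,       1 / 14,  1 / 14, -1 / 9,   0)
  )
}

#' Region anchor coordinates from a landmark set
#'
#' Copies the four anchoring landmarks into per-region anchor points:
#' landmark 34 anchors the nose, landmark 31 anchors both cheeks,
#' landmark 28 the forehead and landmark 9 the chin.
#'
#' @param lm A [landmark_set()].
#' @return A tibble with columns `roi`, `x`, `y` (five rows, region order of
#'   [roi_names()]; the two cheek rows share landmark 31's coordinates).
#' @export
roi_anchors <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  pick <- function(i) c(lm$x[i], lm$y[i])
  nose <- pick(anchor_indices[["nose"]])
  cheeks <- pick(anchor_indices[["cheeks"]])
  forehead <- pick(anchor_indices[["forehead"]])
  chin <- pick(anchor_indices[["chin"]])
  tibble(
    roi = roi_names(),
    x = c(nose[1], cheeks[1], cheeks[1], forehead[1], chin[1]),
    y = c(nose[2], cheeks[2], cheeks[2], forehead[2], chin[2])
  )
}

#' Pixel region for one facial ROI
#'
#' Builds the inclusive rectangular pixel-index range for a region from its
#' anchor point and the detected-face box. Horizontal bounds are the anchor
#' column plus/minus a fixed fraction of the face width `w`; vertical
#' bounds use fractions of the face height `h`:
#'
#' * nose: `x` in `[ax - w/16, ax + w/16]`, `y` in `[ay - h/13, ay]`
#' * right cheek: `x` in `[ax - w/3, ax - w/5]`, `y` in `[ay - h/14, ay + h/14]`
#' * left cheek: `x` in `[ax + w/5, ax + 12w/35]`, `y` in `[ay - h/14, ay + h/14]`
#' * forehead: `x` in `[ax - w/12, ax + w/12]`, `y` in `[ay - h/4, ay - h/9]`
#' * chin: `x` in `[ax - w/12, ax + w/12]`, `y` in `[ay - h/8, ay]`
#'
#' Fractional offsets (and any real-valued anchor) are rounded to the
#' nearest integer, half away from zero. Bounds are clipped to the image;
#' a region entirely outside the image is an error.
#'
#' @param roi One of [roi_names()].
#' @param anchor_x,anchor_y Anchor pixel coordinates (0-based; x = column).
#' @param box A [face_box()] supplying `w` and `h`.
#' @param image_shape Integer `(rows, cols)`.
#' @return An object of class `pixel_region`: a list with inclusive 0-based
#'   bounds `i_lo`, `i_hi` (columns), `j_lo`, `j_hi` (rows) and a `clipped`
#'   flag.
#' @export
roi_region <- function(roi, anchor_x, anchor_y, box, image_shape) {
  roi <- match.arg(roi, roi_names())
  fr <- roi_offset_fractions()
  fr <- fr[fr$roi == roi, ]
  ax <- round_half_out(anchor_x)
  ay <- round_half_out(anchor_y)
  i_lo <- ax + round_half_out(fr$dx_lo * box$w)
  i_hi <- ax + round_half_out(fr$dx_hi * box$w)
  j_lo <- ay + round_half_out(fr$dy_lo * box$h)
  j_hi <- ay + round_half_out(fr$dy_hi * box$h)
  rows <- image_shape[1]; cols <- image_shape[2]
  if (i_hi < 0 || i_lo > cols - 1 || j_hi < 0 || j_lo > rows - 1) {
    stopf("%s region lies entirely outside the %dx%d image", roi, rows, cols,
          class = "thermoface_empty_region")
  }
  clipped <- i_lo < 0 || j_lo < 0 || i_hi > cols - 1 || j_hi > rows - 1
  structure(
    list(i_lo = max(i_lo, 0L), i_hi = min(i_hi, cols - 1L),
         j_lo = max(j_lo, 0L), j_hi = min(j_hi, rows - 1L),
         clipped = clipped),
    class = "pixel_region"
  )
}

#' All five ROI pixel regions for a frame
#'
#' @param lm A [landmark_set()].
#' @param box A [face_box()].
#' @param image_shape Integer `(rows, cols)`.
#' @return Named list of [roi_region()] results, one per region.
#' @export
roi_regions <- function(lm, box, image_shape) {
  anchors <- roi_anchors(lm)
  regions <- purrr::pmap(anchors, function(roi, x, y) {
    roi_region(roi, x, y, box, image_shape)
  })
  setNames(regions, anchors$roi)
}

#' @export
print.pixel_region <- function(x, ...) {
  cat(sprintf("<pixel_region> cols [%d, %d] x rows [%d, %d]%s\n",
              x$i_lo, x$i_hi, x$j_lo, x$j_hi,
              if (x$clipped) " (clipped)" else ""))
  invisible(x)
}
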