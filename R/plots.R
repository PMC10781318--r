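#' Plot an evaluation report as a confusion-matrix heatmap
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(report_levels)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("Overall accuracy %.2f%% (n = %d)",
                      object$overall_accuracy, object$n),
      x = "predicted state", y = "true state") +
    ggplot2::theme_minimal()
}

#' Plot the per-region, per-state temperature summary
#'
#' Mean plus/minus one SD per region and state.
#'
#' @param summary Output of [summarize_by_state()].
#' @return A ggplot object.
#' @export
plot_state_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$roi, y = .data$mean,
                                        colour = .data$phase)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "temperature (°C)",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Overlay the five ROI rectangles on a thermal frame
#'
#' @param frame A [thermal_frame()].
#' @param landmarks,box Optional explicit landmark set / face box;
#'   located via `provider` when omitted.
#' @param provider A [landmark_provider()].
#' @return A ggplot object: temperature raster with region rectangles.
#' @export
plot_roi_regions <- function(frame, landmarks = NULL, box = NULL,
                             provider = landmark_provider()) {
  if (is.null(landmarks) || is.null(box)) {
    det <- detect_landmarks(frame, provider)
    landmarks <- landmarks %||% det$landmarks
    box <- box %||% det$box
  }
  temps <- decode_frame(frame)
  df <- expand.grid(y = seq_len(nrow(temps)) - 1,
                    x = seq_len(ncol(temps)) - 1)
  df$temp <- as.vector(temps)
  regions <- roi_regions(landmarks, box, dim(frame$pixels))
  rects <- purrr::imap_dfr(regions, function(r, roi) {
    tibble(roi = roi, xmin = r$i_lo - 0.5, xmax = r$i_hi + 0.5,
           ymin = r$j_lo - 0.5, ymax = r$j_hi + 0.5)
  })
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$temp)) +
    ggplot2::geom_rect(data = rects,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    colour = .data$roi),
                       fill = NA, linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno",
                                  name = "temp (°C)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
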