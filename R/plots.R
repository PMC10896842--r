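#' Plot ANOVA-F feature weights along the flattened CD feature axis
#'
#' Features recur region-by-region within each time bin; weights of global
#' vs non-global discrimination typically concentrate in the bins nearest
#' the SO trough.
#'
#' @param w Weight vector from [anova_f_weights()].
#' @param dt_ms Bin width of the underlying CD features.
#' @param regions Region labels.
#' @return A ggplot object.
#' @export
plot_feature_weights <- function(w, dt_ms, regions = so_regions()) {
  grid <- cd_feature_grid(dt_ms, regions)
  if (length(w) != nrow(grid)) {
    stop_sostim(
      "weight length %d does not match %d features", length(w), nrow(grid)
    )
  }
  grid$weight <- as.numeric(w)
  ggplot2::ggplot(grid, ggplot2::aes(.data$feature, .data$weight)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$time_ms), size = 0.8) +
    ggplot2::labs(
      x = "feature (time-major)", y = "ANOVA F",
      colour = "time from\ntrough (ms)",
      title = paste0("feature weights (dt = ", dt_ms, " ms)")
    ) +
    ggplot2::theme_minimal()
}
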