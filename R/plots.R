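#' Plot time-lapse growth trajectories
#'
#' Log10 area against time, one line per FOV series, faceted by condition
#' when more than one is present.
#'
#' @param data A measurement tibble.
#' @return A ggplot object.
#' @export
plot_timelapse <- function(data) {
  data <- validate_timelapse(data)
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$time_h, y = .data$log_area,
                 group = interaction(.data$experiment_id, .data$fov_id),
                 colour = .data$experiment_id)
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Time (h)", y = expression(log[10]~area),
                  colour = "Experiment") +
    ggplot2::theme_minimal()
  if (n_distinct(data$condition) > 1) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Plot a margin-of-error design grid
#'
#' MOE against the number of experiments, one line per (FOV, frames)
#' combination, log-scaled vertical axis (the single-experiment margin is
#' orders of magnitude wider than multi-experiment margins).
#'
#' @param grid A tibble from [design_grid()].
#' @return A ggplot object.
#' @export
plot_design_grid <- function(grid) {
  stopifnot(all(c("n_exp", "n_fov", "n_time", "moe") %in% names(grid)))
  grid %>%
    mutate(setting = sprintf("%d FOV, %d frames/h", .data$n_fov,
                             .data$n_time)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$n_exp, y = .data$moe,
                                 colour = .data$setting)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Number of experiments",
                  y = "Margin of error (log10 units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of bootstrap lower confidence limits
#'
#' Histogram of the one-sided lower 95% confidence limits across simulated
#' studies; studies left of zero fail to detect a significant kill.
#'
#' @param x A `bootstrap_validation` object.
#' @return A ggplot object.
#' @export
plot_bootstrap_limits <- function(x) {
  stopifnot(inherits(x, "bootstrap_validation"))
  ggplot2::ggplot(x$studies, ggplot2::aes(x = .data$lower)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Lower one-sided 95% limit for mean LR",
                  y = "Simulated studies") +
    ggplot2::theme_minimal()
}
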