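# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.signal_tracks <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("wps", "coverage", "uend", "dend"),
                              names_to = "track", values_to = "value")
  long$track <- factor(long$track, levels = c("wps", "coverage", "uend", "dend"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "cfDNA per-base signal tracks") +
    ggplot2::theme_minimal()
}

#' Plot a windowed T-squared chart with its control limit and calls
#'
#' @param stats Numeric vector of windowed T-squared values.
#' @param ucl Upper control limit.
#' @param window_bp Window width in bp.
#' @param calls Optional tibble from [apply_run_rules()]; called spans
#'   are shaded.
#' @return A ggplot object.
#' @export
plot_t2_chart <- function(stats, ucl, window_bp = 200L, calls = NULL) {
  df <- tibble::tibble(window = seq_along(stats) - 1L, t2 = stats)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$t2)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = ucl, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "window", y = expression(T^2),
                  title = "Robust Hotelling T² chart") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE, alpha = 0.2, fill = "red",
      ggplot2::aes(xmin = .data$start_window - 0.5,
                   xmax = .data$end_window + 0.5,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.ocr_pipeline <- function(object, ...) {
  df <- dplyr::mutate(
    object$test,
    state = factor(.data$true_class, levels = c(0, 2, 1),
                   labels = c("closed", "partially open", "open")))
  ggplot2::ggplot(df, ggplot2::aes(x = seq_len(nrow(df)), y = .data$st2,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$chart$cl_adjusted,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = 1 - object$chart$eta,
                        linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = "sample", y = expression(ST^2),
                  title = "Sensitized T² statistic by true state",
                  subtitle = "dashed: adjusted CL (red) and 1 - eta (blue)") +
    ggplot2::theme_minimal()
}
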