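#' Plot a conduction-delay histogram
#'
#' Bars of paired-spike counts over signed delay; positive delays are
#' feed-forward, negative feedback. Detected axon peaks can be overlaid.
#'
#' @param object A `delay_histogram`.
#' @param axons Optional `axon_assignments` to mark peaks.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delay_histogram <- function(object, axons = NULL, ...) {
  df <- tibble::tibble(delay_ms = object$bin_centers_ms,
                       count = object$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$delay_ms, .data$count)) +
    ggplot2::geom_col(width = object$bin_width_ms, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "conduction delay (ms)", y = "paired spikes",
                  title = "Tunnel conduction-delay histogram") +
    ggplot2::theme_minimal()
  if (!is.null(axons) && nrow(axons)) {
    p <- p + ggplot2::geom_vline(
      data = as.data.frame(axons),
      ggplot2::aes(xintercept = .data$peak_delay_ms,
                   colour = .data$direction),
      linewidth = 0.8) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot a CCD with its power-law fit
#'
#' Log-log complementary cumulative distribution with the fitted line
#' drawn over the winning fit window.
#'
#' @param object A `ccd`.
#' @param fit Optional `power_law_fit` or `piecewise_ibi_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccd <- function(object, fit = NULL, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$p > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$p)) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t", y = "P(value >= t)",
                  title = "Complementary cumulative distribution") +
    ggplot2::theme_minimal()
  seg <- function(f) {
    tw <- f$fit_window
    tibble::tibble(t = tw, p = 10^(f$alpha * log10(tw) + f$c))
  }
  if (inherits(fit, "power_law_fit")) {
    p <- p + ggplot2::geom_line(data = seg(fit), colour = "firebrick")
  } else if (inherits(fit, "piecewise_ibi_fit")) {
    p <- p +
      ggplot2::geom_line(data = seg(fit$fast), colour = "firebrick") +
      ggplot2::geom_line(data = seg(fit$slow), colour = "steelblue") +
      ggplot2::geom_vline(xintercept = fit$crossover, linetype = 3)
  }
  p
}

#' Plot the functional-connectivity edge distribution
#'
#' Edge weights (mean slope) against reliability (mean R-squared), split
#' by feed-forward/feedback direction class and orientation.
#'
#' @param edges Edge tibble from [build_edges()].
#' @return A ggplot.
#' @export
plot_edges <- function(edges) {
  ggplot2::ggplot(edges,
                  ggplot2::aes(.data$mean_slope, .data$mean_r2,
                               colour = .data$direction_class,
                               shape = .data$orientation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.2, linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0.1, linetype = 2,
                        colour = "grey60") +
    ggplot2::labs(x = "mean slope (weight)", y = "mean R^2 (reliability)",
                  colour = NULL, shape = NULL,
                  title = "Functional connectivity edges") +
    ggplot2::theme_minimal()
}

#' Plot per-region degree balance
#'
#' Mean per-node metric per sub-region, orientation and direction class,
#' from [graph_metrics()] regional aggregates.
#'
#' @param metrics A `graph_metrics` result built with a layout.
#' @param metric Which metric to show.
#' @return A ggplot.
#' @export
plot_region_balance <- function(metrics,
                                metric = c("degree", "slope_centrality",
                                           "r2_centrality")) {
  metric <- match.arg(metric)
  df <- dplyr::filter(metrics$regions, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$region, .data$mean_per_node,
                                   fill = .data$direction_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~orientation, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = paste("mean", metric, "per well node"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
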