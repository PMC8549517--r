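#' Plot a junction histogram along a circle
#'
#' Chimeric-read junction counts along the circle (5'DRJ to 3'DRJ), with
#' the HIM interval shaded; zooming on the HIM shows the two J hotspots.
#'
#' @param hist A [junction_histogram()].
#' @param him_only Restrict the x-axis to the HIM interval (with margin).
#' @return A ggplot object.
#' @export
plot_junction_histogram <- function(hist, him_only = FALSE) {
  him <- attr(hist, "him")
  df <- as_tibble(hist)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey20") +
    ggplot2::labs(x = "circle position (bp, 5'DRJ → 3'DRJ)",
                  y = "chimeric reads",
                  title = unique(df$segment_id)) +
    ggplot2::theme_minimal()
  if (!is.null(him) && !anyNA(him)) {
    p <- p + ggplot2::annotate("rect", xmin = him[1], xmax = him[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
    if (him_only) {
      pad <- 25
      p <- p + ggplot2::coord_cartesian(xlim = c(him[1] - pad, him[2] + pad))
    }
  }
  p
}

#' @method autoplot junction_histogram
#' @export
autoplot.junction_histogram <- function(object, ...) {
  plot_junction_histogram(object, ...)
}

#' Plot observed versus expected microhomology-length distributions
#'
#' Observed counts as bars, null expectation (rescaled to the observed
#' total) as points — the classic bars-and-asterisks comparison.
#'
#' @param x An `mh_comparison` object ([compare_mh_distributions()]).
#' @return A ggplot object.
#' @export
plot_mh_comparison <- function(x) {
  tab <- x$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey20") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "red",
                        shape = 8, size = 2) +
    ggplot2::labs(x = "microhomology length (bp)", y = "chimeric reads") +
    ggplot2::theme_minimal()
}

#' @method autoplot mh_comparison
#' @export
autoplot.mh_comparison <- function(object, ...) plot_mh_comparison(object)

#' Plot the window-occupancy spectrum against the Poisson expectation
#'
#' @param x An `ie_poisson_test` object.
#' @return A ggplot object.
#' @export
plot_window_occupancy <- function(x) {
  stopifnot(inherits(x, "ie_poisson_test"), !x$degenerate)
  df <- tidyr::pivot_longer(x$occupancy, c("observed", "expected"),
                            names_to = "which", values_to = "windows")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$windows,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(observed = "grey20",
                                          expected = "red")) +
    ggplot2::labs(x = "integration events per window", y = "windows",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot ie_poisson_test
#' @export
autoplot.ie_poisson_test <- function(object, ...) {
  plot_window_occupancy(object)
}
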