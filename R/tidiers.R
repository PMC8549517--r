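#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the Poisson window test
#'
#' @param x An `ie_poisson_test`.
#' @param ... Unused.
#' @return The per-occupancy-class observed/expected tibble.
#' @method tidy ie_poisson_test
#' @export
tidy.ie_poisson_test <- function(x, ...) {
  if (x$degenerate) return(tibble(k = integer(), observed = numeric(),
                                  expected = numeric()))
  x$occupancy
}

#' @rdname tidy.ie_poisson_test
#' @return For `glance()`: a one-row tibble with `lambda`, `n_windows`,
#'   `statistic`, `df`, `p_value`, `max_plausible_count`.
#' @method glance ie_poisson_test
#' @export
glance.ie_poisson_test <- function(x, ...) {
  tibble(lambda = x$lambda, n_windows = x$n_windows,
         statistic = x$statistic, df = x$df, p_value = x$p_value,
         max_plausible_count = x$max_plausible_count)
}

#' Tidy the depth-IE correlation
#'
#' @param x An `ie_depth_cor`.
#' @param ... Unused.
#' @return The per-segment depth/IE ratio tibble.
#' @method tidy ie_depth_cor
#' @export
tidy.ie_depth_cor <- function(x, ...) x$ratios

#' @rdname tidy.ie_depth_cor
#' @return For `glance()`: one row with `rho`, `p_value`, `n`.
#' @method glance ie_depth_cor
#' @export
glance.ie_depth_cor <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n)
}

#' Tidy the microhomology comparison
#'
#' @param x An `mh_comparison`.
#' @param ... Unused.
#' @return The per-length observed/expected/ratio tibble.
#' @method tidy mh_comparison
#' @export
tidy.mh_comparison <- function(x, ...) x$table

#' @rdname tidy.mh_comparison
#' @method glance mh_comparison
#' @export
glance.mh_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         pooled_bins = x$pooled_bins)
}
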