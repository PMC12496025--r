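#' Plot bundle achievement over time by country
#'
#' Monthly mean achievement with vertical markers at the policy start
#' (April 2010) and the subsequent bonus increases.
#'
#' @param rows Analysis rows from [build_outcomes()].
#' @param outcome Outcome column.
#' @return A ggplot object.
#' @export
plot_achievement <- function(rows, outcome = "bundle_met") {
  series <- achievement_series(rows, outcome)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$admission_date,
                                       y = .data$achievement,
                                       colour = .data$country)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = as.Date(c("2010-04-01", "2011-04-01",
                                               "2012-04-01")),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Admission month", y = "Share achieving outcome",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted policy model
#'
#' Plots the treatment-effect coefficients (or all coefficients) with
#' cluster-robust confidence intervals.
#'
#' @param object A `cb_fit`.
#' @param effects_only Show only the named effect coefficients?
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cb_fit
#' @export
autoplot.cb_fit <- function(object, effects_only = TRUE, conf.level = 0.95, ...) {
  td <- tidy(object, conf.int = TRUE, conf.level = conf.level)
  if (effects_only && !is.null(object$effect_terms)) {
    td <- dplyr::filter(td, .data$term %in% object$effect_terms)
  }
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Map of provider decision regions in cost space
#'
#' Shades the `(c1, c2)` plane by comparison region (one-process-under-
#' itemized vs both/none-under-bundled, and the unchanged corners) for given
#' itemized prices and cost synergy, with the bundled price set to
#' `p1 + p2`.
#'
#' @param p1,p2 Itemized prices.
#' @param s Cost synergy.
#' @param upper Upper bound of the plotted cost range.
#' @param n Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_cost_regions <- function(p1, p2, s = 0, upper = max(p1 + p2, 1), n = 200) {
  grid <- tidyr::expand_grid(c1 = seq(0, upper, length.out = n),
                             c2 = seq(0, upper, length.out = n)) |>
    dplyr::mutate(s = s)
  grid <- classify_region(grid, p1, p2)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$c1, y = .data$c2,
                                     fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "Cost of process 1", y = "Cost of process 2",
                  fill = "Region") +
    ggplot2::theme_minimal()
}
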