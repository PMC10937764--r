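#' Tornado diagram
#'
#' Horizontal bars spanning each parameter's one-way low/high result,
#' sorted by swing, with the base-case value as a reference line.
#'
#' @param x A [tornado()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_tornado <- function(x, ...) {
  d <- dplyr::mutate(x, parameter = stats::reorder(.data$parameter, .data$swing))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$low_result, xend = .data$high_result,
                   yend = .data$parameter),
      linewidth = 4, colour = "steelblue", lineend = "butt"
    ) +
    ggplot2::geom_vline(xintercept = d$base_result[1], linetype = "dashed") +
    ggplot2::labs(
      x = if (identical(attr(x, "quantity"), "icer")) {
        "ICER (GBP per inpatient-day averted)"
      } else {
        "Expected cost (GBP)"
      },
      y = NULL,
      title = "One-way sensitivity (tornado)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @param object A [tornado()] table.
#' @export
autoplot.stonecea_tornado <- function(object, ...) plot_tornado(object, ...)

#' Plot joint sensitivity ranges
#'
#' Point-and-interval display of each quantity's base value and its joint
#' deterministic sensitivity interval.
#'
#' @param x A [joint_range()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sensitivity_ranges <- function(x, ...) {
  d <- dplyr::mutate(x, label = paste0(.data$quantity, ": ", .data$strategy))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$base), size = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free", ncol = 1) +
    ggplot2::labs(x = "GBP (cost) / GBP per day averted (ICER)", y = NULL,
                  title = sprintf("Joint ±%d%% deterministic sensitivity",
                                  round(100 * d$fraction[1]))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_sensitivity_ranges
#' @param object A [joint_range()] table.
#' @export
autoplot.stonecea_sensitivity <- function(object, ...) plot_sensitivity_ranges(object, ...)
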