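#' Plot the cost-effectiveness plane
#'
#' Scatter of PSA draws in (DALYs averted, incremental cost) space, with an
#' optional willingness-to-pay line through the origin.
#'
#' @param psa `psa_result`.
#' @param wtp Optional willingness-to-pay slope (USD/DALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = NULL) {
  draws <- psa$draws
  p <- ggplot2::ggplot(draws,
                       ggplot2::aes(x = dalys_averted,
                                    y = incremental_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "DALYs averted", y = "Incremental cost (2014 USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_points Tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_points) {
  ggplot2::ggplot(ceac_points,
                  ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per DALY averted)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high ICER, ranked by span.
#'
#' @param tornado Tibble from [one_way()].
#' @param top Number of parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 12) {
  t <- utils::head(tornado[order(-tornado$span), ], top)
  t$name <- factor(t$name, levels = rev(t$name))
  ggplot2::ggplot(t, ggplot2::aes(y = name)) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low,
                                       xend = icer_high,
                                       yend = name),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "Cost per DALY averted (2014 USD)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
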