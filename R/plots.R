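quadrant_fills <- c(lowE_lowT = "#74add1", lowE_highT = "#fee090",
                    highE_lowT = "#a6d96a", highE_highT = "#f46d43")

#' Portfolio plot
#'
#' Threat score (x) against EBSA likelihood score (y) with the four
#' portfolio quadrants shaded and the data-uncertainty indices drawn as
#' symmetric error bars. Bars may spill outside the 1-5 score range;
#' that is the point of drawing them — an uncertain score may belong to
#' either category.
#'
#' @param assessment a `seamount_assessment` from [assess_seamounts()].
#' @param label label points with seamount names (default TRUE).
#' @return A ggplot object.
#' @examples
#' case_study_seamounts() |> assess_seamounts() |> plot_portfolio()
#' @export
plot_portfolio <- function(assessment, label = TRUE) {
  d <- portfolio_plot_data(assessment)
  quads <- tibble::tibble(
    cell = factor(names(quadrant_fills), levels = names(quadrant_fills)),
    xmin = c(-Inf, 3, -Inf, 3), xmax = c(3, Inf, 3, Inf),
    ymin = c(-Inf, -Inf, 3, 3), ymax = c(3, 3, Inf, Inf)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_rect(
      data = quads,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax, fill = .data$cell),
      inherit.aes = FALSE, alpha = 0.35
    ) +
    ggplot2::scale_fill_manual(values = quadrant_fills, name = "portfolio") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$yerr, ymax = .data$y + .data$yerr),
      width = 0.05, linewidth = 0.3
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$x - .data$xerr, xmax = .data$x + .data$xerr),
      height = 0.05, linewidth = 0.3
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(xlim = c(0.5, 5.5), ylim = c(0.5, 5.5)) +
    ggplot2::labs(x = "Threat score", y = "EBSA likelihood score") +
    ggplot2::theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$seamount),
                                vjust = -0.8, size = 3)
  }
  p
}

#' @rdname plot_portfolio
#' @param object a `seamount_assessment`.
#' @param ... passed to [plot_portfolio()].
#' @export
autoplot.seamount_assessment <- function(object, ...) {
  plot_portfolio(object, ...)
}

#' Component decomposition ("radar") plot
#'
#' Faceted polar display of the two per-seamount component profiles: the
#' EBSA typology profile (0-5) and the per-group maximum threat (1-5).
#'
#' @param data long record tibble.
#' @param config an [ebsa_config()].
#' @return A ggplot object.
#' @examples
#' case_study_seamounts() |>
#'   dplyr::filter(seamount %in% c("Sedlo", "Gorringe")) |>
#'   plot_radar()
#' @export
plot_radar <- function(data, config = ebsa_config()) {
  d <- radar_data(data, config)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis, y = .data$value,
                                  group = .data$profile,
                                  colour = .data$profile,
                                  fill = .data$profile)) +
    ggplot2::geom_polygon(alpha = 0.25) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 5) +
    ggplot2::facet_wrap(~seamount) +
    ggplot2::scale_colour_manual(
      values = c(ebsa = "#e6b800", threat = "#d7301f")) +
    ggplot2::scale_fill_manual(
      values = c(ebsa = "#e6b800", threat = "#d7301f")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
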