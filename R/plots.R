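# QC plots. Deliberately simple: the package's figures are for checking a
# run, not for publication.

#' Plot a nitrogen budget
#'
#' Bars of the apparent nitrogen balance per treatment, faceted by year and
#' shaded by the surplus/deficit classification, with the near-equilibrium
#' band marked.
#'
#' @param object A `"nitrogen_budget"` from [nitrogen_budget()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot nitrogen_budget
autoplot.nitrogen_budget <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$balance, fill = .data$balance_class
  )) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf, ymin = thr[1], ymax = thr[2],
      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$year)) +
    ggplot2::labs(
      x = NULL, y = "Apparent N balance (kg/ha)", fill = NULL,
      title = "Apparent nitrogen balance by treatment"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot seasonal N2O flux series
#'
#' Plot-level flux time series per treatment (lines per replicate),
#' faceted by pattern and year; flagged low-quality slope fits are marked.
#'
#' @param flux A flux tibble, e.g. from [chamber_fluxes()] (optionally
#'   already position-weighted).
#' @param w_ridge Ridge weight used to collapse positions. Default 0.5.
#' @return A ggplot object.
#' @export
plot_flux_series <- function(flux, w_ridge = 0.5) {
  plot_flux <- position_weighted_flux(flux, w_ridge)
  ggplot2::ggplot(plot_flux, ggplot2::aes(
    x = .data$date, y = .data$flux_ug_m2_h,
    colour = factor(.data$n_rate), group = interaction(.data$n_rate, .data$replicate)
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(ggplot2::vars(.data$pattern), ggplot2::vars(.data$year),
      scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = expression(N[2] * O ~ flux ~ (mu * g ~ m^-2 ~ h^-1)),
      colour = "N rate (kg/ha)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an LSD letter display
#'
#' Level means with their compact letters, in descending order.
#'
#' @param object A tibble from [lsd_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot nbudget_lsd
autoplot.nbudget_lsd <- function(object, ...) {
  plot_lsd(object)
}

#' @rdname autoplot.nbudget_lsd
#' @param groups A tibble from [lsd_groups()].
#' @export
plot_lsd <- function(groups) {
  df <- dplyr::mutate(groups, level = factor(.data$level, levels = .data$level))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
      vjust = -0.4, size = 3.5) +
    ggplot2::labs(x = NULL, y = "Mean") +
    ggplot2::theme_minimal()
}
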