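#' Plot a diel flux composite
#'
#' Points and error bars (mean +/- SE) of a two-hour diel composite, one
#' panel per grouping combination when `facets` columns are present.
#'
#' @param composite Output of [diel_composite()].
#' @param facets Optional character vector of columns to facet by
#'   (e.g. `c("habitat", "gas")`).
#' @return A ggplot object.
#' @export
plot_diel_composite <- function(composite, facets = intersect(c("habitat", "gas"), names(composite))) {
  p <- ggplot2::ggplot(composite,
                       ggplot2::aes(x = hour_bin + 1, y = mean_val)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_val - se,
                                        ymax = mean_val + se), width = 0.6) +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4), limits = c(0, 24)) +
    ggplot2::labs(x = "Hour of day (2-h bins)",
                  y = expression(Flux ~ (mg ~ m^-2 ~ d^-1))) +
    ggplot2::theme_minimal()
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  }
  p
}

#' Plot daily net fluxes
#'
#' @param daily Output of [daily_fluxes()].
#' @return A ggplot object.
#' @export
plot_daily_fluxes <- function(daily) {
  ggplot2::ggplot(daily, ggplot2::aes(x = date, y = mean_flux)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_flux - se_flux,
                                          ymax = mean_flux + se_flux)) +
    ggplot2::facet_grid(gas ~ habitat, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(Daily ~ net ~ flux ~ (mg ~ m^-2 ~ d^-1))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot Tukey HSD simultaneous confidence intervals
#'
#' @param object A `coastalghg_tukey` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coastalghg_tukey
#' @export
autoplot.coastalghg_tukey <- function(object, ...) {
  object <- as_tibble(object)
  object$pair <- paste(object$group_b, "-", object$group_a)
  ggplot2::ggplot(object, ggplot2::aes(x = difference, y = pair)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Difference in means (simultaneous CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a net greenhouse-gas balance
#'
#' Bar chart of CO2 flux, CO2-equivalent CH4 flux and the net balance per
#' habitat, all in g CO2-eq.
#'
#' @param object A `coastalghg_balance` tibble from [ghg_balance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coastalghg_balance
#' @export
autoplot.coastalghg_balance <- function(object, ...) {
  long <- object %>%
    as_tibble() %>%
    select(habitat, f_co2, co2eq_ch4, net_balance) %>%
    tidyr::pivot_longer(-habitat, names_to = "component", values_to = "value") %>%
    mutate(component = factor(component,
                              levels = c("f_co2", "co2eq_ch4", "net_balance"),
                              labels = c("CO2", "CO2-eq CH4", "Net GHG")))
  ggplot2::ggplot(long, ggplot2::aes(x = habitat, y = value, fill = component)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(g ~ CO[2] * -eq ~ m^-2),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
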