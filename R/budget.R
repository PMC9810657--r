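#' Default season lengths
#'
#' Quarter-year season lengths (365.25 / 4 days each) used when
#' extrapolating seasonal campaign means to an annual cumulative flux.
#'
#' @return Named numeric vector, days per season.
#' @export
default_season_lengths <- function() {
  c(spring = 91.3125, summer = 91.3125, fall = 91.3125, winter = 91.3125)
}

#' CO2-equivalent CH4 flux
#'
#' Converts a CH4 mass flux to a CO2-equivalent flux by multiplying with
#' the sustained-flux global warming potential (SGWP) of CH4, 45 on a
#' mass basis over a 100-year horizon.  The sustained-flux metric (rather
#' than the one-time pulse GWP) applies because these ecosystems exchange
#' greenhouse gases with the atmosphere continuously.  Only the 100-year
#' horizon is supported; the factor is read from the gas constants file,
#' not hard-coded.
#'
#' @param f_ch4 CH4 flux in mass units (any area-time basis); sign is
#'   preserved.
#' @param horizon Time horizon in years; must be 100.
#' @return CO2-equivalent flux on the same area-time basis.
#' @examples
#' co2_equivalent(0.55)  # 24.75
#' @export
co2_equivalent <- function(f_ch4, horizon = 100) {
  if (!identical(as.numeric(horizon), 100)) {
    abort("Only the 100-year sustained-flux horizon is supported.")
  }
  f_ch4 * gas_info("CH4")$sgwp_100
}

#' Annual cumulative flux from seasonal summaries
#'
#' First-order annual flux estimate: each season's mean daily flux is
#' multiplied by the season length and summed; the propagated error
#' treats seasons as independent,
#' `sqrt(sum((daily_se * length)^2))`.  Units convert from mg m^-2 d^-1
#' to g m^-2 y^-1.
#'
#' @param summaries Tibble with columns `habitat`, `season`
#'   (spring/summer/fall/winter), `gas`, `daily_mean`, `daily_se`
#'   (mg m^-2 d^-1).  All four seasons must be present per habitat/gas.
#' @param season_lengths Named vector of season lengths in days
#'   (default [default_season_lengths()]).
#' @return A tibble `habitat, gas, cumulative_flux, propagated_error`
#'   (g m^-2 y^-1).
#' @export
annual_cumulative <- function(summaries, season_lengths = default_season_lengths()) {
  needed <- c("habitat", "season", "gas", "daily_mean", "daily_se")
  missing_cols <- setdiff(needed, names(summaries))
  if (length(missing_cols)) {
    abort(sprintf("`summaries` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  total <- sum(season_lengths)
  if (abs(total - 365.25) > 1.5) {
    abort(sprintf("Season lengths sum to %g days; expected ~365.25.", total))
  }
  check <- summaries %>%
    group_by(habitat, gas) %>%
    summarise(miss = paste(setdiff(names(season_lengths), season),
                           collapse = ", "), .groups = "drop") %>%
    filter(miss != "")
  if (nrow(check)) {
    abort(sprintf(
      "Missing season(s) for %s: %s.",
      paste(check$habitat, check$gas, sep = "/", collapse = "; "),
      paste(unique(check$miss), collapse = ", ")
    ))
  }
  summaries %>%
    mutate(season_length_days = unname(season_lengths[season])) %>%
    group_by(habitat, gas) %>%
    summarise(
      cumulative_flux = sum(daily_mean * season_length_days) / 1000,
      propagated_error = sqrt(sum((daily_se * season_length_days)^2)) / 1000,
      .groups = "drop"
    )
}

#' Net greenhouse-gas balance and offset metric
#'
#' Combines a CO2 flux and a CH4 flux (same area-time basis, e.g. annual
#' g m^-2 y^-1) into the net greenhouse-gas balance
#' `net = f_co2 + SGWP * f_ch4` (g CO2-eq) and the offset metric:
#' when the CO2 flux is an uptake (`f_co2 < 0`), the offset percentage
#' `100 * co2eq_ch4 / |f_co2|` states how much of the carbon sink
#' capacity is counterbalanced by CO2-equivalent CH4 emission
#' (`offset_type = "offset"`); when the CO2 flux is a source
#' (`f_co2 > 0`), the same ratio states by how much CH4 augments the CO2
#' emission (`offset_type = "augmentation"`).  For `f_co2 = 0` the metric
#' is undefined and returned missing.
#'
#' @param f_co2 CO2 flux (vector), positive = efflux to atmosphere.
#' @param f_ch4 CH4 mass flux (vector, recycled), same area-time basis.
#' @param habitat Optional habitat labels.
#' @param period Label for the accounting period (default `"annual"`).
#' @param horizon SGWP time horizon in years; must be 100.
#' @return A tibble of class `coastalghg_balance` with columns `habitat`,
#'   `period`, `f_co2`, `f_ch4`, `co2eq_ch4`, `net_balance`,
#'   `offset_percent`, `offset_type`, `reason`.
#' @examples
#' ghg_balance(f_co2 = c(-71, 30), f_ch4 = c(0.55, 0.38),
#'             habitat = c("mixed_vegetation", "bare_sediment"))
#' @export
ghg_balance <- function(f_co2, f_ch4, habitat = NULL, period = "annual",
                        horizon = 100) {
  n <- max(length(f_co2), length(f_ch4))
  f_co2 <- rep_len(f_co2, n)
  f_ch4 <- rep_len(f_ch4, n)
  if (is.null(habitat)) habitat <- rep(NA_character_, n)
  co2eq <- co2_equivalent(f_ch4, horizon)
  out <- tibble(
    habitat = rep_len(habitat, n),
    period = rep_len(period, n),
    f_co2 = f_co2,
    f_ch4 = f_ch4,
    co2eq_ch4 = co2eq,
    net_balance = f_co2 + co2eq,
    offset_percent = dplyr::if_else(f_co2 == 0, NA_real_,
                                    100 * co2eq / abs(f_co2)),
    offset_type = case_when(
      is.na(f_co2) ~ NA_character_,
      f_co2 < 0 ~ "offset",
      f_co2 > 0 ~ "augmentation",
      TRUE ~ NA_character_
    ),
    reason = dplyr::if_else(!is.na(f_co2) & f_co2 == 0,
                            "offset undefined for zero CO2 flux",
                            NA_character_)
  )
  class(out) <- c("coastalghg_balance", class(out))
  out
}

#' Reporting-precision balance table
#'
#' Rounds a greenhouse-gas balance to reporting precision: integer
#' g CO2-eq for fluxes and balances, integer percent for offsets.  Full
#' precision is retained in the input object; this is a view.
#'
#' @param balance A `coastalghg_balance` tibble from [ghg_balance()].
#' @return A tibble rounded for reporting.
#' @export
balance_table <- function(balance) {
  balance %>%
    as_tibble() %>%
    mutate(
      f_co2 = round(f_co2),
      co2eq_ch4 = round(co2eq_ch4),
      net_balance = round(net_balance),
      offset_percent = round(offset_percent)
    ) %>%
    select(habitat, period, f_co2, co2eq_ch4, net_balance, offset_percent,
           offset_type)
}

#' @export
print.coastalghg_balance <- function(x, ...) {
  cat("Net greenhouse-gas balance (g CO2-eq per area per period)\n")
  print(balance_table(x), ...)
  invisible(x)
}

#' Seasonal summaries from daily net fluxes
#'
#' Aggregates a daily flux table into per-season summaries (mean of daily
#' means, SE across days) ready for [annual_cumulative()].
#'
#' @param daily Tibble from [daily_fluxes()] with an added `season`
#'   column.
#' @return A tibble `habitat, season, gas, daily_mean, daily_se, n_days`.
#' @export
summarize_seasons <- function(daily) {
  if (!"season" %in% names(daily)) {
    abort("`daily` needs a `season` column (spring/summer/fall/winter).")
  }
  daily %>%
    filter(!is.na(mean_flux)) %>%
    group_by(habitat, season, gas) %>%
    summarise(
      daily_mean = mean(mean_flux),
      daily_se = stats::sd(mean_flux) / sqrt(dplyr::n()),
      n_days = dplyr::n(),
      .groups = "drop"
    )
}
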