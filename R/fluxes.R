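#' Pipeline configuration
#'
#' Collects the tunable quality-control and integration parameters of the
#' flux pipeline in one list.
#'
#' @param purge_s Transition purge after each phase/station switch, s.
#' @param width_s Averaging interval for flux means, s (15 min default).
#' @param min_coverage Minimum fraction of a day's intervals required for
#'   a daily net flux.
#' @param max_gap_s Maximum allowed time gap for the nearest-neighbour
#'   join of environmental data onto gas records, s.
#' @param water_min,air_min,tol_min Nominal cycle window durations and
#'   tolerance, minutes.
#' @param pressure_atm Total pressure used to convert dry mole fractions
#'   (ppm) to partial pressures (micro-atm) when the environment series
#'   carries no pressure column.
#' @return A named list of class `coastalghg_config`.
#' @export
qc_config <- function(purge_s = 300, width_s = 900, min_coverage = 0.5,
                      max_gap_s = 900, water_min = 35, air_min = 10,
                      tol_min = 3, pressure_atm = 1) {
  structure(
    list(
      purge_s = purge_s, width_s = width_s, min_coverage = min_coverage,
      max_gap_s = max_gap_s, water_min = water_min, air_min = air_min,
      tol_min = tol_min, pressure_atm = pressure_atm
    ),
    class = "coastalghg_config"
  )
}

#' Join environmental data onto gas records by nearest time
#'
#' Attaches, to every gas record, the environmental observation closest in
#' time.  Records farther than `max_gap_s` seconds from any environmental
#' observation get missing environment values.
#'
#' @param records Gas-record tibble.
#' @param env Environment tibble (see [read_env_series()]).
#' @param max_gap_s Maximum allowed gap, seconds (default 900).
#' @return `records` with the environment columns appended.
#' @export
join_environment <- function(records, env, max_gap_s = 900) {
  if (!nrow(env)) {
    abort("Environment series is empty.")
  }
  env <- arrange(env, timestamp)
  ts_r <- as.numeric(records$timestamp)
  ts_e <- as.numeric(env$timestamp)
  idx <- findInterval(ts_r, ts_e)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ts_e))
  pick <- ifelse(abs(ts_r - ts_e[lo]) <= abs(ts_r - ts_e[hi]), lo, hi)
  gap <- abs(ts_r - ts_e[pick])
  env_cols <- env[pick, setdiff(names(env), "timestamp")]
  env_cols[gap > max_gap_s, ] <- NA
  dplyr::bind_cols(records, env_cols)
}

#' Instantaneous sea-air fluxes from a raw gas stream
#'
#' Runs the full record-level pipeline: cycle parsing, transition purging,
#' per-cycle atmospheric reference, nearest-time environment join, wind
#' adjustment to 10 m, solubility, Schmidt number, gas transfer velocity,
#' and the bulk flux equation.  One output row per usable water-phase
#' record and gas.
#'
#' @param records Gas-record tibble (see [read_gas_stream()]).
#' @param env Environment tibble (see [read_env_series()]).
#' @param config Pipeline configuration from [qc_config()].
#' @return A tibble with one row per water record and gas: `timestamp`,
#'   `habitat`, `deployment`, `cycle_index`, `gas`, `x_ppm`, `x_air_ppm`,
#'   `p_sea_uatm`, `p_air_uatm`, `u10_ms`, `sc`, `k_cmh`, `k_ms`, `k0`,
#'   `flux_mg_m2_d` (positive = efflux to the atmosphere).
#' @export
compute_fluxes <- function(records, env, config = qc_config()) {
  cycles <- parse_cycles(records, config$water_min, config$air_min,
                         config$tol_min)
  records <- assign_cycles(records, cycles)
  records <- filter_transitions(records, cycles, config$purge_s)
  air_ref <- cycle_air_reference(records, cycles)
  water <- records %>%
    filter(phase == "water", qc_flag == "ok", !is.na(cycle_index)) %>%
    left_join(
      select(air_ref, deployment, cycle_index, xco2_air_ppm = "xco2_air_ppm",
             xch4_air_ppm = "xch4_air_ppm"),
      by = c("deployment", "cycle_index")
    )
  water <- join_environment(water, env, config$max_gap_s)
  if (!"pressure_atm" %in% names(water)) {
    water$pressure_atm <- config$pressure_atm
  }
  water$pressure_atm[is.na(water$pressure_atm)] <- config$pressure_atm
  water$u10_ms <- adjust_wind_to_10m(water$wind_ms, water$ustar_ms, water$zu_m)

  per_gas <- function(g, x_col, x_air_col) {
    d <- water
    d$gas <- g
    d$x_ppm <- d[[x_col]]
    d$x_air_ppm <- d[[x_air_col]]
    d$p_sea_uatm <- d$x_ppm * d$pressure_atm
    d$p_air_uatm <- d$x_air_ppm * d$pressure_atm
    d$sc <- schmidt_number(g, d$twater_c, d$salinity)
    sol <- solubility(g, d$twater_c + 273.15, d$salinity)
    d$k0 <- sol$k0
    kt <- gas_transfer_velocity(d$u10_ms, d$sc)
    d$k_cmh <- kt$k_cmh
    d$k_ms <- kt$k_ms
    d$flux_mg_m2_d <- sea_air_flux(g, d$k_ms, d$k0, d$p_sea_uatm, d$p_air_uatm)
    d
  }
  bind_rows(
    per_gas("CO2", "xco2_ppm", "xco2_air_ppm"),
    per_gas("CH4", "xch4_ppm", "xch4_air_ppm")
  ) %>%
    select(timestamp, habitat, deployment, cycle_index, gas, x_ppm,
           x_air_ppm, p_sea_uatm, p_air_uatm, twater_c, salinity, u10_ms,
           sc, k_cmh, k_ms, k0, flux_mg_m2_d) %>%
    arrange(gas, timestamp)
}

#' Daily net sea-air fluxes from a raw gas stream
#'
#' Convenience wrapper chaining [compute_fluxes()], 15-min averaging
#' ([resample_mean()]) and daily integration ([daily_net_flux()]).
#'
#' @inheritParams compute_fluxes
#' @return A tibble `habitat, date, gas, mean_flux, se_flux, n_intervals,
#'   coverage, reason` (units mg m^-2 d^-1).
#' @export
daily_fluxes <- function(records, env, config = qc_config()) {
  compute_fluxes(records, env, config) %>%
    group_by(habitat, gas) %>%
    resample_mean(flux_mg_m2_d, width_s = config$width_s) %>%
    group_by(habitat, gas) %>%
    daily_net_flux(min_coverage = config$min_coverage,
                   width_s = config$width_s) %>%
    select(habitat, gas, date, mean_flux, se_flux, n_intervals, coverage,
           reason)
}

#' Run the flux pipeline on CSV inputs
#'
#' Reads a gas-record CSV and an environment CSV and returns (optionally
#' writes) the daily net flux table with schema
#' `habitat,date,gas,mean_flux_mg_m2_d,se_flux,n`.
#'
#' @param gas_csv,env_csv Input file paths.
#' @param out Optional output CSV path.
#' @param config Pipeline configuration from [qc_config()].
#' @return The daily flux tibble, invisibly when `out` is given.
#' @export
flux_pipeline <- function(gas_csv, env_csv, out = NULL, config = qc_config()) {
  daily <- daily_fluxes(read_gas_stream(gas_csv), read_env_series(env_csv),
                        config)
  if (!is.null(out)) {
    daily %>%
      select(habitat, date, gas, mean_flux_mg_m2_d = "mean_flux",
             se_flux = "se_flux", n = "n_intervals") %>%
      readr::write_csv(out)
    return(invisible(daily))
  }
  daily
}
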