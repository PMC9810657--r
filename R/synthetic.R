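#' Synthetic campaign presets
#'
#' Scenario presets for the synthetic-campaign generator.  Each preset
#' encodes one habitat/season deployment: water temperature, salinity
#' (drawn in 6.6-7.0, the brackish range of the study region), dissolved
#' CH4 level (tens of nmol L^-1, persistently supersaturated), a diel
#' pCO2 cycle whose undersaturation peaks in the early afternoon
#' (13:00-17:00 window), a Weibull wind climate with hour-scale
#' persistence, instrument noise, and the analyzer response-lag constant.
#' The `*_flux_lo/hi` columns are calibration envelopes: the per-habitat
#' seasonal daily net flux ranges the presets are built to land in
#' (mg m^-2 d^-1).
#'
#' @return A tibble, one row per preset.
#' @export
scenario_presets <- function() {
  tibble::tribble(
    ~preset, ~habitat, ~season, ~start_date,
    ~twater_c, ~ch4_nmol, ~ch4_diel_amp_nmol, ~dpco2_mean_uatm,
    ~pco2_diel_amp_uatm, ~ch4_flux_lo, ~ch4_flux_hi, ~co2_flux_lo, ~co2_flux_hi,
    "macroalgae-spring", "macroalgae", "spring", "2020-05-20",
    8, 15, 2, -100, 80, 0.1, 1.8, -763, 0,
    "macroalgae-summer", "macroalgae", "summer", "2020-07-06",
    17, 53, 3, -150, 120, 0.1, 1.8, -763, 0,
    "macroalgae-fall", "macroalgae", "fall", "2020-10-22",
    10, 45, 3, -120, 60, 0.1, 1.8, -763, 0,
    "macroalgae-winter", "macroalgae", "winter", "2020-12-01",
    3, 12, 1, 40, 20, 0.1, 1.8, 0, 390,
    "mixedvegetation-summer", "mixed_vegetation", "summer", "2020-07-06",
    18, 56, 3, -180, 130, 0.1, 2.9, -763, 0,
    "baresediment-summer", "bare_sediment", "summer", "2020-07-06",
    18, 50, 3, 60, 40, 0.1, 2.5, 0, 390
  )
}

#' Build a synthetic scenario configuration
#'
#' Starts from a named preset (see [scenario_presets()]) and applies any
#' overrides.  All stochastic draws of the generator flow from the single
#' `seed`, so a fixed seed yields byte-identical campaigns.
#'
#' @param preset Preset name.
#' @param n_days Number of simulated days (one habitat deployment).
#' @param seed Integer seed (< 2^31 - 2).
#' @param ... Overrides for any configuration field; unknown keys raise a
#'   configuration error.
#' @return A list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config("macroalgae-summer", n_days = 1, seed = 42)
#' cfg$ch4_nmol
#' @export
scenario_config <- function(preset = "macroalgae-summer", n_days = 1,
                            seed = 1, ...) {
  presets <- scenario_presets()
  if (!preset %in% presets$preset) {
    abort(sprintf("Unknown preset \"%s\". Available: %s.", preset,
                  paste(presets$preset, collapse = ", ")))
  }
  row <- as.list(presets[presets$preset == preset, ])
  cfg <- c(row, list(
    n_days = n_days, seed = seed,
    salinity_range = c(6.6, 7.0),
    twater_diel_amp_c = 0.8,
    twater_noise_c = 0.15,
    pco2_air_uatm = 415,
    xch4_air_ppm = 1.95,
    pco2_min_hour = 15,          # pCO2 minimum (peak uptake 13:00-17:00)
    pco2_noise_uatm = 8,
    ch4_noise_nmol = 1.5,
    wind_shape = 2, wind_scale = 5,
    wind_persistence_min = 60,
    ustar_drag = sqrt(1.3e-3),
    zu_m = 1.5,
    pressure_atm = 1,
    cycle_water_s = 2100, cycle_air_s = 600,
    log_dt_s = 10,
    lag_tau_s = 60,
    noise_sd_xco2 = 0.5, noise_sd_xch4 = 0.001,
    n_low_flow_records = 0
  ))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Configuration error: unknown key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  bad <- character()
  pos <- c("n_days", "pco2_air_uatm", "xch4_air_ppm",
           "ch4_nmol", "wind_shape", "wind_scale", "wind_persistence_min",
           "zu_m", "pressure_atm", "cycle_water_s", "cycle_air_s", "log_dt_s")
  for (key in pos) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 || cfg[[key]] <= 0) {
      bad <- c(bad, key)
    }
  }
  nonneg <- c("pco2_noise_uatm", "ch4_noise_nmol", "lag_tau_s", "twater_noise_c",
              "noise_sd_xco2", "noise_sd_xch4", "ch4_diel_amp_nmol", "twater_diel_amp_c",
              "pco2_diel_amp_uatm", "n_low_flow_records")
  for (key in nonneg) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 || cfg[[key]] < 0) {
      bad <- c(bad, key)
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed) || abs(cfg$seed) >= 2^31 - 2) {
    bad <- c(bad, "seed")
  }
  if (length(bad)) {
    abort(sprintf("Configuration error: invalid value(s) for key(s): %s.",
                  paste(unique(bad), collapse = ", ")))
  }
  invisible(cfg)
}

# stationary AR(1) series: marginal sd `sd`, lag-1 correlation `phi`
ar1_series <- function(n, sd, phi) {
  if (sd == 0) return(rep(0, n))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate ground-truth fields for a synthetic campaign
#'
#' Generates the 1-min environmental forcing (water temperature with a
#' weak diel cycle, constant brackish salinity, AR(1)-persistent Weibull
#' wind with derived friction velocity, constant pressure) and the true
#' dissolved-gas fields: a diel sinusoidal pCO2 with its minimum at the
#' configured afternoon hour, and a persistently supersaturated CH4
#' concentration converted to partial pressure through the gas
#' solubility.  The truth ledger stores, per minute and gas, the inputs
#' (p_sea, p_air, k, K0) and the instantaneous flux computed from them
#' with the bulk flux equation, plus the trapezoid-integrated true daily
#' net flux and the true cycle boundaries.
#'
#' @param config A [scenario_config()] object.
#' @return A list with elements `env` (environment tibble at 1-min
#'   resolution), `ledger` (per-minute truth, long by gas), `daily`
#'   (true daily net fluxes), `cycles` (true cycle windows), and
#'   `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, simulate_truth_impl(config))
}

simulate_truth_impl <- function(config) {
  n_min <- config$n_days * 1440L
  start <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  ts <- start + 60 * (seq_len(n_min) - 1L)
  hour <- (as.numeric(ts) - as.numeric(start)) %% 86400 / 3600
  phi_w <- exp(-1 / config$wind_persistence_min)

  twater <- config$twater_c -
    config$twater_diel_amp_c * cos(2 * pi * (hour - 16) / 24) +
    ar1_series(n_min, config$twater_noise_c, phi_w)
  salinity <- runif(1, config$salinity_range[1], config$salinity_range[2])

  z <- ar1_series(n_min, 1, phi_w)
  u10 <- qweibull(pnorm(z), shape = config$wind_shape,
                  scale = config$wind_scale)
  ustar <- config$ustar_drag * u10
  kappa <- physical_constants()$kappa
  wind_at_zu <- u10 - (ustar / kappa) * log(10 / config$zu_m)

  env <- tibble(
    timestamp = ts,
    twater_c = twater,
    salinity = salinity,
    wind_ms = wind_at_zu,
    ustar_ms = ustar,
    zu_m = config$zu_m,
    pressure_atm = config$pressure_atm
  )

  diel <- -cos(2 * pi * (hour - config$pco2_min_hour) / 24)
  pco2_sea <- config$pco2_air_uatm + config$dpco2_mean_uatm +
    config$pco2_diel_amp_uatm * diel +
    ar1_series(n_min, config$pco2_noise_uatm, phi_w)
  pco2_sea <- pmax(pco2_sea, 5)
  ch4_nmol <- pmax(
    config$ch4_nmol + config$ch4_diel_amp_nmol * diel +
      ar1_series(n_min, config$ch4_noise_nmol, phi_w),
    0.5
  )

  k0_ch4 <- solubility("CH4", twater + 273.15, salinity)$k0
  pch4_sea <- ch4_nmol / k0_ch4     # nmol L^-1 over mol m^-3 atm^-1 -> uatm
  p_air <- c(CO2 = config$pco2_air_uatm,
             CH4 = config$xch4_air_ppm * config$pressure_atm)

  ledger_gas <- function(g, p_sea) {
    sc <- schmidt_number(g, twater, salinity)
    kt <- gas_transfer_velocity(u10, sc)
    k0 <- solubility(g, twater + 273.15, salinity)$k0
    tibble(
      timestamp = ts, habitat = config$habitat, gas = g,
      p_sea_uatm = p_sea, p_air_uatm = p_air[[g]],
      sc = sc, k_ms = kt$k_ms, k0 = k0,
      flux_mg_m2_d = sea_air_flux(g, kt$k_ms, k0, p_sea, p_air[[g]])
    )
  }
  ledger <- bind_rows(ledger_gas("CO2", pco2_sea),
                      ledger_gas("CH4", pch4_sea))

  daily <- ledger %>%
    mutate(date = lubridate::as_date(timestamp)) %>%
    group_by(habitat, gas, date) %>%
    summarise(true_daily_flux = trapezoid_mean(flux_mg_m2_d),
              .groups = "drop")

  cycle_len <- config$cycle_water_s + config$cycle_air_s
  n_cycles <- floor(config$n_days * 86400 / cycle_len)
  ws <- start + cycle_len * (seq_len(n_cycles) - 1L)
  cycles <- tibble(
    habitat = config$habitat, cycle_index = seq_len(n_cycles),
    water_start = ws, water_end = ws + config$cycle_water_s,
    air_start = ws + config$cycle_water_s, air_end = ws + cycle_len
  )

  list(env = env, ledger = ledger, daily = daily, cycles = cycles,
       config = config)
}

# trapezoid-rule mean of an evenly spaced series
trapezoid_mean <- function(x) {
  n <- length(x)
  if (n == 1) return(x)
  (sum(x) - (x[1] + x[n]) / 2) / (n - 1)
}

#' Render a raw analyzer stream from simulated truth
#'
#' Emulates the observation process: 35/10-min water/air cycles logged
#' every 10 s, a first-order analyzer response lag after each phase
#' switch (time constant `lag_tau_s`), and additive Gaussian instrument
#' noise on the dry mole fractions.  Records within two lag constants of
#' a phase switch are indexed as lag-contaminated in the returned truth
#' attributes.  All randomness derives from the scenario seed.
#'
#' @param truth Output of [simulate_truth()].
#' @param config The same [scenario_config()] used for the truth.
#' @return A gas-record tibble (`timestamp, phase, habitat, xco2_ppm,
#'   xch4_ppm, flag`) with attribute `contaminated` (logical vector
#'   marking lag-affected records).
#' @export
render_stream <- function(truth, config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed + 1L, render_stream_impl(truth, config))
}

render_stream_impl <- function(truth, config) {
  start <- truth$env$timestamp[1]
  dt <- config$log_dt_s
  n_rec <- config$n_days * 86400 / dt
  ts <- start + dt * (seq_len(n_rec) - 1L)
  s <- as.numeric(ts) - as.numeric(start)
  cycle_len <- config$cycle_water_s + config$cycle_air_s
  pos <- s %% cycle_len
  phase <- ifelse(pos < config$cycle_water_s, "water", "air")

  target_for <- function(g, x_air) {
    led <- truth$ledger[truth$ledger$gas == g, ]
    p_sea <- stats::approx(as.numeric(led$timestamp), led$p_sea_uatm,
                           xout = as.numeric(ts), rule = 2)$y
    ifelse(phase == "water", p_sea / config$pressure_atm, x_air)
  }
  lag_filter <- function(target) {
    if (config$lag_tau_s == 0) return(target)
    a <- 1 - exp(-dt / config$lag_tau_s)
    as.numeric(stats::filter(a * target, 1 - a, method = "recursive",
                             init = target[1]))
  }
  x_co2 <- lag_filter(target_for("CO2", config$pco2_air_uatm /
                                   config$pressure_atm)) +
    rnorm(n_rec, 0, config$noise_sd_xco2)
  x_ch4 <- lag_filter(target_for("CH4", config$xch4_air_ppm)) +
    rnorm(n_rec, 0, config$noise_sd_xch4)

  flag <- rep("ok", n_rec)
  if (config$n_low_flow_records > 0) {
    i0 <- sample.int(n_rec - config$n_low_flow_records, 1)
    flag[seq(i0, length.out = config$n_low_flow_records)] <- "low_flow"
  }
  contaminated <- (pos < 2 * config$lag_tau_s) |
    (pos >= config$cycle_water_s &
       pos < config$cycle_water_s + 2 * config$lag_tau_s)

  out <- tibble(
    timestamp = ts, phase = phase, habitat = config$habitat,
    xco2_ppm = pmax(x_co2, 0.1), xch4_ppm = pmax(x_ch4, 0.001),
    flag = flag
  )
  attr(out, "contaminated") <- contaminated
  out
}

#' Simulate a complete synthetic campaign
#'
#' Runs [simulate_truth()] and [render_stream()] and optionally writes the
#' gas stream, environment series and truth ledger as CSV files in the
#' schemas consumed by the flux pipeline.
#'
#' @param config A [scenario_config()] object.
#' @param out_dir Optional directory; when given, writes `gas.csv`,
#'   `env.csv`, `truth_daily.csv` and `truth_minute.csv` there.
#' @return A list `gas` (raw record tibble, `flag` column named as in the
#'   CSV schema), `env`, `truth` (ledger, daily, cycles, contaminated).
#' @export
simulate_campaign <- function(config, out_dir = NULL) {
  truth <- simulate_truth(config)
  gas <- render_stream(truth, config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(gas, file.path(out_dir, "gas.csv"))
    readr::write_csv(truth$env, file.path(out_dir, "env.csv"))
    readr::write_csv(truth$daily, file.path(out_dir, "truth_daily.csv"))
    readr::write_csv(truth$ledger, file.path(out_dir, "truth_minute.csv"))
  }
  list(
    gas = gas, env = truth$env,
    truth = list(ledger = truth$ledger, daily = truth$daily,
                 cycles = truth$cycles,
                 contaminated = attr(gas, "contaminated"))
  )
}

#' Recover daily net fluxes from one synthetic campaign
#'
#' End-to-end helper used in validation: simulates a campaign, runs the
#' full QC + flux pipeline on the rendered stream, and joins the
#' estimated daily net fluxes with the ledger truth.
#'
#' @param config A [scenario_config()] object.
#' @param qc A [qc_config()] list.
#' @return A tibble with one row per day and gas: `habitat`, `date`,
#'   `gas`, estimated `mean_flux` and `se_flux`, and `true_daily_flux`.
#' @export
recover_campaign <- function(config, qc = qc_config()) {
  sim <- simulate_campaign(config)
  records <- sim$gas %>% rename(qc_flag = flag)
  daily <- daily_fluxes(records, sim$env, qc)
  daily %>%
    left_join(sim$truth$daily, by = c("habitat", "gas", "date")) %>%
    select(habitat, date, gas, mean_flux, se_flux, n_intervals,
           true_daily_flux = "true_daily_flux")
}
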