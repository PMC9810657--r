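# fixtures are built in code: a constant-valued cycle stream, a constant
# environment series, and raw data with exact summary moments

make_cycle_stream <- function(n_cycles, start = as.POSIXct("2020-07-06", tz = "UTC"),
                              dt = 10, water_s = 2100, air_s = 600,
                              water_co2 = 300, air_co2 = 415,
                              water_ch4 = 30, air_ch4 = 1.95,
                              habitat = "macroalgae",
                              truncate_last_water_s = NULL) {
  cycle_len <- water_s + air_s
  ts <- start + seq(0, n_cycles * cycle_len - dt, by = dt)
  pos <- as.numeric(ts - start, units = "secs") %% cycle_len
  water <- pos < water_s
  if (!is.null(truncate_last_water_s)) {
    # keep only part of the last water window and drop its air window
    last_start <- (n_cycles - 1) * cycle_len
    keep <- as.numeric(ts - start, units = "secs") <
      last_start + truncate_last_water_s
    keep[seq_len(length(ts))[as.numeric(ts - start, units = "secs") < last_start]] <- TRUE
    ts <- ts[keep]; water <- water[keep]
  }
  tibble::tibble(
    timestamp = ts,
    phase = ifelse(water, "water", "air"),
    habitat = habitat,
    xco2_ppm = ifelse(water, water_co2, air_co2),
    xch4_ppm = ifelse(water, water_ch4, air_ch4),
    qc_flag = "ok"
  )
}

make_env_constant <- function(start = as.POSIXct("2020-07-06", tz = "UTC"),
                              n_min = 1440, twater_c = 17, salinity = 6.8,
                              wind_ms = 4, ustar_ms = 0.15, zu_m = 1.5,
                              pressure_atm = 1) {
  tibble::tibble(
    timestamp = start + 60 * (seq_len(n_min) - 1),
    twater_c = twater_c, salinity = salinity, wind_ms = wind_ms,
    ustar_ms = ustar_ms, zu_m = zu_m, pressure_atm = pressure_atm
  )
}

# raw data with exactly the requested mean, sd (n-1 denominator) and n
raw_from_summary <- function(m, s, n) {
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}

random_group_summaries <- function(k = 3) {
  tibble::tibble(
    label = paste0("g", seq_len(k)),
    mean = stats::rnorm(k, 50, 5),
    sd = stats::runif(k, 0.5, 3),
    n = sample(5:40, k, replace = TRUE)
  )
}
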