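#' Read a raw equilibrator/CRDS gas stream
#'
#' Reads the gas-record CSV schema
#' `timestamp,phase,habitat,xco2_ppm,xch4_ppm,flag` (one row per logged
#' 10-s record).  `phase` must be `water` or `air`; `flag` is one of
#' `ok`, `transition`, `malfunction`, `low_flow` (missing flag column is
#' treated as all-`ok`).  Timestamps must be strictly increasing.
#'
#' @param path CSV file path.
#' @param tz Time zone used to parse timestamps; campaigns use the local
#'   clock, default `"UTC"` keeps clock time as-is.
#' @return A tibble of equilibrator records with column `qc_flag`.
#' @export
read_gas_stream <- function(path, tz = "UTC") {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      phase = readr::col_character(),
      habitat = readr::col_character(),
      xco2_ppm = readr::col_double(),
      xch4_ppm = readr::col_double(),
      .default = readr::col_character()
    ),
    locale = readr::locale(tz = tz),
    progress = FALSE
  )
  if (!"flag" %in% names(df)) df$flag <- "ok"
  df <- df %>%
    rename(qc_flag = flag) %>%
    select(timestamp, phase, habitat, xco2_ppm, xch4_ppm, qc_flag)
  validate_gas_stream(df)
  df
}

validate_gas_stream <- function(df) {
  bad_phase <- setdiff(unique(df$phase), c("water", "air"))
  if (length(bad_phase)) {
    abort(sprintf(
      "Structural format error: unknown phase value(s): %s.",
      paste(bad_phase, collapse = ", ")
    ))
  }
  bad_flag <- setdiff(unique(df$qc_flag),
                      c("ok", "transition", "malfunction", "low_flow"))
  if (length(bad_flag)) {
    abort(sprintf("Unknown qc flag value(s): %s.",
                  paste(bad_flag, collapse = ", ")))
  }
  if (is.unsorted(df$timestamp, strictly = TRUE)) {
    abort("Gas stream timestamps must be strictly increasing.")
  }
  ok <- df$qc_flag == "ok"
  if (any(ok & (is.na(df$xco2_ppm) | df$xco2_ppm <= 0), na.rm = TRUE) ||
      any(ok & (is.na(df$xch4_ppm) | df$xch4_ppm <= 0), na.rm = TRUE)) {
    abort("ok-flagged records must have positive CO2 and CH4 mole fractions.")
  }
  invisible(df)
}

#' Read an environmental/meteorological series
#'
#' Reads the environment CSV schema
#' `timestamp,twater_c,salinity,wind_ms,ustar_ms,zu_m,pressure_atm`.
#' A missing `pressure_atm` column defaults to 1 atm (the analyzer
#' measured a dried gas stream, so no water-vapour correction applies).
#'
#' @inheritParams read_gas_stream
#' @return A tibble of environmental records.
#' @export
read_env_series <- function(path, tz = "UTC") {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      .default = readr::col_double()
    ),
    locale = readr::locale(tz = tz),
    progress = FALSE
  )
  needed <- c("timestamp", "twater_c", "salinity", "wind_ms", "ustar_ms", "zu_m")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(sprintf("Environment file lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"pressure_atm" %in% names(df)) df$pressure_atm <- 1
  if (is.unsorted(df$timestamp)) {
    df <- arrange(df, timestamp)
  }
  df
}
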