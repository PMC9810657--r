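#' Parse water/air measurement cycles from an equilibrator stream
#'
#' Segments a gas-record stream into measurement cycles: a window of
#' water-equilibrated headspace measurements (nominally 35 min) followed
#' by a window of ambient-air measurements (nominally 10 min), i.e. one
#' complete 45-min cycle.  Records are grouped into habitat deployments
#' (maximal blocks of consecutive records at the same habitat) and cycles
#' are indexed consecutively within each deployment.  All windows are
#' half-open `[start, end)`.
#'
#' A final water window with no (or a truncated) air window yields a cycle
#' with status `"partial"`; windows much longer than nominal are flagged
#' `"irregular"`.  An air run at the start of a deployment has no parent
#' water window; its records are orphans (no cycle).
#'
#' @param records Gas-record tibble (see [read_gas_stream()]).
#' @param water_min,air_min Nominal water/air window durations, minutes.
#' @param tol_min Tolerance on window durations, minutes.
#' @return A tibble with one row per cycle: `habitat`, `deployment`,
#'   `cycle_index`, `water_start`, `water_end`, `air_start`, `air_end`
#'   (`air_*` are `NA` for a water-only partial cycle) and `status`
#'   (`complete`, `partial`, `irregular`).
#' @export
parse_cycles <- function(records, water_min = 35, air_min = 10, tol_min = 3) {
  validate_gas_stream(records)
  if (nrow(records) == 0) {
    return(tibble(
      habitat = character(), deployment = integer(), cycle_index = integer(),
      water_start = as.POSIXct(character(), tz = "UTC"),
      water_end = as.POSIXct(character(), tz = "UTC"),
      air_start = as.POSIXct(character(), tz = "UTC"),
      air_end = as.POSIXct(character(), tz = "UTC"),
      status = character()
    ))
  }
  dt_med <- stats::median(as.numeric(diff(records$timestamp)))
  if (!is.finite(dt_med) || is.na(dt_med)) dt_med <- 10
  records$deployment <- deployment_id(records$habitat)
  # maximal runs of constant (deployment, phase)
  run_key <- paste(records$deployment, records$phase)
  run_id <- cumsum(c(TRUE, run_key[-1] != run_key[-length(run_key)]))
  runs <- records %>%
    mutate(run_id = run_id) %>%
    group_by(run_id) %>%
    summarise(
      deployment = first(deployment), habitat = first(habitat),
      phase = first(phase), start = min(timestamp), last = max(timestamp),
      .groups = "drop"
    ) %>%
    mutate(end = lead(start, default = last[dplyr::n()] + dt_med))
  cycles <- runs %>%
    group_by(deployment) %>%
    dplyr::group_modify(~ pair_runs(.x)) %>%
    ungroup() %>%
    mutate(status = cycle_status(
      water_start, water_end, air_start, air_end,
      water_min * 60, air_min * 60, tol_min * 60
    )) %>%
    select(habitat, deployment, cycle_index, water_start, water_end,
           air_start, air_end, status)
  attr(cycles, "nominal") <- c(water_s = water_min * 60, air_s = air_min * 60)
  cycles
}

deployment_id <- function(habitat) {
  cumsum(c(TRUE, habitat[-1] != habitat[-length(habitat)]))
}

# pair each water run with the immediately following air run of the same
# deployment; a trailing water run becomes a partial (air-less) cycle
pair_runs <- function(runs) {
  n <- nrow(runs)
  is_water <- runs$phase == "water"
  water_idx <- which(is_water)
  if (!length(water_idx)) {
    return(tibble(
      habitat = character(), cycle_index = integer(),
      water_start = runs$start[0], water_end = runs$start[0],
      air_start = runs$start[0], air_end = runs$start[0]
    ))
  }
  has_air <- water_idx + 1L <= n & !is_water[pmin(water_idx + 1L, n)]
  tibble(
    habitat = runs$habitat[water_idx],
    cycle_index = seq_along(water_idx),
    water_start = runs$start[water_idx],
    water_end = runs$end[water_idx],
    air_start = dplyr::if_else(has_air, runs$start[pmin(water_idx + 1L, n)],
                               runs$start[NA_integer_]),
    air_end = dplyr::if_else(has_air, runs$end[pmin(water_idx + 1L, n)],
                             runs$start[NA_integer_])
  )
}

cycle_status <- function(ws, we, as_, ae, water_s, air_s, tol_s) {
  wdur <- as.numeric(we) - as.numeric(ws)
  adur <- as.numeric(ae) - as.numeric(as_)
  case_when(
    is.na(adur) ~ "partial",
    wdur < water_s - tol_s | adur < air_s - tol_s ~ "partial",
    wdur > water_s + tol_s | adur > air_s + tol_s ~ "irregular",
    TRUE ~ "complete"
  )
}

#' Assign records to measurement cycles
#'
#' Labels each record with the `deployment` and `cycle_index` of the cycle
#' window containing its timestamp; records outside every cycle window
#' (e.g. a leading air run) get `NA` (orphans).
#'
#' @param records Gas-record tibble.
#' @param cycles Cycle tibble from [parse_cycles()].
#' @return `records` with columns `deployment` and `cycle_index` added.
#' @export
assign_cycles <- function(records, cycles) {
  records$deployment <- deployment_id(records$habitat)
  records$cycle_index <- NA_integer_
  for (dep in unique(cycles$deployment)) {
    cyc <- cycles[cycles$deployment == dep, ]
    sel <- which(records$deployment == dep)
    if (!length(sel) || !nrow(cyc)) next
    ts <- as.numeric(records$timestamp[sel])
    idx <- findInterval(ts, as.numeric(cyc$water_start))
    end <- ifelse(is.na(cyc$air_end), as.numeric(cyc$water_end),
                  as.numeric(cyc$air_end))
    inside <- idx > 0 & ts < end[pmax(idx, 1L)]
    records$cycle_index[sel[inside]] <- cyc$cycle_index[idx[inside]]
  }
  records
}

#' Flag transition periods after phase and station switches
#'
#' The analyzer needs time to respond to the sharp concentration change at
#' every water/air phase switch and at every move between habitats, so
#' records within `purge_s` seconds after any window start are flagged
#' `"transition"`.  Records already flagged `malfunction` or `low_flow`
#' are left as-is (they stay excluded downstream).  Increasing the purge
#' never un-flags a record.
#'
#' @param records Gas-record tibble.
#' @param cycles Cycle tibble from [parse_cycles()].
#' @param purge_s Purge duration after each switch, seconds (default 300).
#' @return `records` with `qc_flag` updated.
#' @export
filter_transitions <- function(records, cycles, purge_s = 300) {
  if (!is.numeric(purge_s) || length(purge_s) != 1 || purge_s < 0) {
    abort("`purge_s` must be a single non-negative number.")
  }
  complete <- cycles[cycles$status == "complete", ]
  if (nrow(complete)) {
    win <- c(
      as.numeric(complete$water_end) - as.numeric(complete$water_start),
      as.numeric(complete$air_end) - as.numeric(complete$air_start)
    )
    if (purge_s >= min(win)) {
      abort(sprintf(
        "Configuration error: purge (%g s) is at least as long as the shortest phase window (%g s).",
        purge_s, min(win)
      ))
    }
  }
  if (purge_s == 0 || !nrow(cycles)) {
    return(records)
  }
  starts <- sort(as.numeric(c(cycles$water_start,
                              cycles$air_start[!is.na(cycles$air_start)])))
  ts <- as.numeric(records$timestamp)
  idx <- findInterval(ts, starts)
  in_purge <- idx > 0 & (ts - starts[pmax(idx, 1L)]) < purge_s
  flag <- records$qc_flag == "ok" & in_purge
  records$qc_flag[flag] <- "transition"
  records
}

#' Per-cycle atmospheric reference mole fractions
#'
#' Averages the ok-flagged ambient-air records of each cycle's air window.
#' This mean is the atmospheric reference applied to the adjacent water
#' window of the same cycle (the nearest-in-time atmospheric measurement).
#'
#' @param records Gas-record tibble, already labelled by [assign_cycles()]
#'   and purged by [filter_transitions()].
#' @param cycles Cycle tibble from [parse_cycles()].
#' @return A tibble `habitat, deployment, cycle_index, xco2_air_ppm,
#'   xch4_air_ppm, n_air`; cycles whose air window has no usable record
#'   get `NA` means.
#' @export
cycle_air_reference <- function(records, cycles) {
  if (!"cycle_index" %in% names(records)) {
    records <- assign_cycles(records, cycles)
  }
  air_means <- records %>%
    filter(phase == "air", qc_flag == "ok", !is.na(cycle_index)) %>%
    group_by(deployment, cycle_index) %>%
    summarise(
      xco2_air_ppm = mean(xco2_ppm),
      xch4_air_ppm = mean(xch4_ppm),
      n_air = dplyr::n(),
      .groups = "drop"
    )
  cycles %>%
    select(habitat, deployment, cycle_index) %>%
    left_join(air_means, by = c("deployment", "cycle_index")) %>%
    mutate(n_air = dplyr::coalesce(n_air, 0L))
}
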