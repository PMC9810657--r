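#' Average a timestamped series onto regular intervals
#'
#' Averages a value column over half-open intervals `[t, t + width_s)`
#' aligned to clock boundaries (midnight-anchored).  Intervals inside the
#' observed span with no contributing record are emitted as missing rows.
#' Respects existing `dplyr` groups (e.g. habitat, gas): interval filling
#' and averaging happen within each group.
#'
#' @param df A tibble with a `POSIXct` time column; may be grouped.
#' @param value Column to average (tidy-eval).
#' @param width_s Interval width in seconds (default 900 = 15 min).
#' @param time_col Name of the time column (default `"timestamp"`).
#' @return A tibble with columns `interval` (interval start), `mean_val`,
#'   `sd_val`, `n_obs`, plus the grouping columns.
#' @export
resample_mean <- function(df, value, width_s = 900, time_col = "timestamp") {
  if (!is.numeric(width_s) || length(width_s) != 1 || width_s <= 0) {
    abort("`width_s` must be a single positive number.")
  }
  value <- enquo(value)
  grp <- dplyr::group_vars(df)
  out <- df %>%
    mutate(interval = floor_interval(.data[[time_col]], width_s)) %>%
    group_by(interval, .add = TRUE) %>%
    summarise(
      mean_val = mean(!!value, na.rm = TRUE),
      sd_val = stats::sd(!!value, na.rm = TRUE),
      n_obs = sum(!is.na(!!value)),
      .groups = "drop"
    ) %>%
    mutate(
      mean_val = dplyr::if_else(n_obs > 0, mean_val, NA_real_),
      sd_val = dplyr::if_else(n_obs > 1, sd_val, dplyr::if_else(n_obs == 1, 0, NA_real_))
    )
  # fill interior gaps with missing intervals, per group
  fill_one <- function(d) {
    full <- tibble(interval = seq(min(d$interval), max(d$interval), by = width_s))
    left_join(full, d, by = "interval") %>%
      mutate(n_obs = dplyr::coalesce(n_obs, 0L))
  }
  if (length(grp)) {
    out <- out %>%
      group_by(across(all_of(grp))) %>%
      dplyr::group_modify(~ fill_one(.x)) %>%
      ungroup()
  } else if (nrow(out)) {
    out <- fill_one(out)
  }
  out
}

floor_interval <- function(ts, width_s) {
  num <- as.numeric(ts)
  structure(floor(num / width_s) * width_s,
            class = c("POSIXct", "POSIXt"), tzone = attr(ts, "tzone"))
}

#' Diel composite in two-hour bins
#'
#' Bins interval means (typically the 15-min flux means) into twelve
#' two-hour blocks of local clock time, bin `b` covering hours
#' `[2b, 2b+2)`, and reports the mean and standard error over the
#' contributing interval means.  Respects existing groups.
#'
#' @param df Tibble of interval means; may be grouped.
#' @param value Column holding the interval means (tidy-eval).
#' @param time_col Name of the interval-start time column.
#' @return A tibble with `hour_bin` (0, 2, ..., 22), `mean_val`, `se`,
#'   `n_obs`, plus grouping columns.  Empty input yields an empty tibble.
#' @export
diel_composite <- function(df, value, time_col = "interval") {
  value <- enquo(value)
  grp <- dplyr::group_vars(df)
  df %>%
    mutate(hour_bin = (lubridate::hour(.data[[time_col]]) %/% 2L) * 2L) %>%
    group_by(hour_bin, .add = TRUE) %>%
    summarise(
      mean_val = mean(!!value, na.rm = TRUE),
      se = stats::sd(!!value, na.rm = TRUE) / sqrt(sum(!is.na(!!value))),
      n_obs = sum(!is.na(!!value)),
      .groups = "drop"
    ) %>%
    mutate(
      mean_val = dplyr::if_else(n_obs > 0, mean_val, NA_real_),
      se = dplyr::if_else(n_obs > 1, se, dplyr::if_else(n_obs == 1, 0, NA_real_))
    ) %>%
    arrange(across(all_of(grp)), hour_bin)
}

#' Daily net flux with coverage control
#'
#' Integrates interval flux means (already expressed per day, mg m^-2
#' d^-1) to a daily net flux: the mean over the day's interval means, with
#' the standard error computed from the spread of those interval means
#' (SE = SD / sqrt(n)).  Days covering less than `min_coverage` of the
#' possible intervals are emitted as missing with a reason.  Respects
#' existing groups (habitat, gas).
#'
#' @param df Tibble of interval means (columns `interval`, `mean_val`),
#'   e.g. from [resample_mean()]; may be grouped.
#' @param min_coverage Minimum fraction of the day's intervals that must
#'   hold a non-missing mean (default 0.5).
#' @param width_s Interval width used upstream, seconds (default 900).
#' @return A tibble with `date`, `mean_flux`, `se_flux`, `n_intervals`,
#'   `coverage`, `reason` (`NA` when the day is valid), plus grouping
#'   columns.
#' @export
daily_net_flux <- function(df, min_coverage = 0.5, width_s = 900) {
  if (min_coverage < 0 || min_coverage > 1) {
    abort("`min_coverage` must lie in [0, 1].")
  }
  slots_per_day <- 86400 / width_s
  df %>%
    mutate(date = lubridate::as_date(interval)) %>%
    group_by(date, .add = TRUE) %>%
    summarise(
      mean_flux = mean(mean_val, na.rm = TRUE),
      se_flux = stats::sd(mean_val, na.rm = TRUE) / sqrt(sum(!is.na(mean_val))),
      n_intervals = sum(!is.na(mean_val)),
      .groups = "drop"
    ) %>%
    mutate(
      coverage = n_intervals / slots_per_day,
      reason = dplyr::if_else(coverage >= min_coverage, NA_character_,
                              "insufficient_coverage"),
      mean_flux = dplyr::if_else(is.na(reason), mean_flux, NA_real_),
      se_flux = dplyr::if_else(is.na(reason) & n_intervals > 1, se_flux, NA_real_)
    )
}
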