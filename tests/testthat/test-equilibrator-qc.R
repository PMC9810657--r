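test_that("cycle parsing recovers exact 35/10-min windows", {
  stream <- make_cycle_stream(3)
  cycles <- parse_cycles(stream)
  expect_equal(nrow(cycles), 3)
  expect_equal(cycles$status, rep("complete", 3))
  expect_equal(cycles$cycle_index, 1:3)
  expect_equal(as.numeric(cycles$water_end - cycles$water_start,
                          units = "secs"), rep(2100, 3))
  expect_equal(as.numeric(cycles$air_end - cycles$air_start,
                          units = "secs"), rep(600, 3))
  # every record lands in exactly one cycle, no orphans
  labelled <- assign_cycles(stream, cycles)
  expect_false(any(is.na(labelled$cycle_index)))
})

test_that("a truncated final cycle is flagged partial", {
  stream <- make_cycle_stream(3, truncate_last_water_s = 900)
  cycles <- parse_cycles(stream)
  expect_equal(nrow(cycles), 3)
  expect_equal(cycles$status, c("complete", "complete", "partial"))
  expect_true(is.na(cycles$air_start[3]))
})

test_that("a leading air run yields orphan records, unknown phases error", {
  stream <- make_cycle_stream(2)
  head_air <- stream[stream$phase == "air", ][1:5, ]
  head_air$timestamp <- stream$timestamp[1] - rev(seq_len(5)) * 10
  with_lead <- dplyr::bind_rows(head_air, stream)
  cycles <- parse_cycles(with_lead)
  expect_equal(nrow(cycles), 2)
  labelled <- assign_cycles(with_lead, cycles)
  expect_equal(sum(is.na(labelled$cycle_index)), 5)

  bad <- stream
  bad$phase[3] <- "sludge"
  expect_error(parse_cycles(bad), "phase")
})

test_that("parsing matches the synthetic generator's cycle ledger", {
  cfg <- scenario_config("macroalgae-summer", n_days = 1, seed = 3)
  sim <- simulate_campaign(cfg)
  cycles <- parse_cycles(dplyr::rename(sim$gas, qc_flag = flag))
  truth <- sim$truth$cycles
  expect_equal(nrow(cycles), nrow(truth))
  expect_equal(cycles$water_start, truth$water_start)
  expect_equal(cycles$water_end, truth$water_end)
  expect_equal(cycles$air_end, truth$air_end)
})

test_that("transition purging flags exactly the purge window and is monotone", {
  stream <- make_cycle_stream(2)
  cycles <- parse_cycles(stream)
  expect_identical(filter_transitions(stream, cycles, purge_s = 0), stream)

  purged <- filter_transitions(stream, cycles, purge_s = 300)
  # with 10-s logging, offsets 0..290 after each of the 4 window starts
  expect_equal(sum(purged$qc_flag == "transition"), 4 * 30)
  first_water <- purged[purged$timestamp < stream$timestamp[1] + 2100, ]
  flagged_offsets <- as.numeric(
    first_water$timestamp[first_water$qc_flag == "transition"] -
      stream$timestamp[1], units = "secs")
  expect_equal(flagged_offsets, seq(0, 290, 10))
  # monotone: larger purge keeps every previously flagged record flagged
  more <- filter_transitions(stream, cycles, purge_s = 450)
  expect_true(all(which(purged$qc_flag == "transition") %in%
                    which(more$qc_flag == "transition")))
  # malfunction records stay excluded, never re-flagged
  stream2 <- stream
  stream2$qc_flag[5] <- "low_flow"
  purged2 <- filter_transitions(stream2, cycles, purge_s = 300)
  expect_equal(purged2$qc_flag[5], "low_flow")
  expect_error(filter_transitions(stream, cycles, purge_s = 700),
               "Configuration")
})

test_that("purging covers the generator's lag-contaminated records", {
  cfg <- scenario_config("macroalgae-summer", n_days = 1, seed = 5)
  sim <- simulate_campaign(cfg)
  records <- dplyr::rename(sim$gas, qc_flag = flag)
  cycles <- parse_cycles(records)
  purged <- filter_transitions(records, cycles,
                               purge_s = 2 * cfg$lag_tau_s)
  flagged <- purged$qc_flag == "transition"
  expect_true(all(flagged[sim$truth$contaminated]))
})

test_that("interval averaging matches closed-form window means", {
  start <- as.POSIXct("2020-07-06", tz = "UTC")
  # constant series: same constant everywhere, zero SD
  const <- tibble::tibble(timestamp = start + 0:599, value = 3.5)
  out <- resample_mean(const, value, width_s = 60)
  expect_equal(out$mean_val, rep(3.5, 10))
  expect_equal(out$sd_val, rep(0, 10))
  expect_equal(out$n_obs, rep(60L, 10))
  # two records in one interval
  two <- tibble::tibble(timestamp = start + c(5, 20), value = c(1, 3))
  expect_equal(resample_mean(two, value, width_s = 60)$mean_val, 2)
  # 1-Hz sinusoid against the closed-form discrete window average
  om <- 2 * pi / 3600
  tt <- 0:7199
  sine <- tibble::tibble(timestamp = start + tt,
                         value = 10 + sin(om * tt))
  got <- resample_mean(sine, value, width_s = 300)
  n <- 300
  t0 <- seq(0, 7199, 300)
  analytic <- 10 + sin(om * t0 + om * (n - 1) / 2) *
    sin(n * om / 2) / (n * sin(om / 2))
  expect_equal(got$mean_val, analytic, tolerance = 1e-9)
  # interior empty intervals are emitted as missing
  gappy <- tibble::tibble(timestamp = start + c(10, 70, 200), value = 1)
  gout <- resample_mean(gappy, value, width_s = 60)
  expect_equal(nrow(gout), 4)
  expect_true(is.na(gout$mean_val[3]))
  expect_equal(gout$n_obs[3], 0L)
})

test_that("diel composite bins two-hour blocks and preserves the mean", {
  start <- as.POSIXct("2020-07-06", tz = "UTC")
  q15 <- tibble::tibble(
    interval = start + 900 * (0:95),
    mean_val = 2
  )
  comp <- diel_composite(q15, mean_val)
  expect_equal(nrow(comp), 12)
  expect_equal(comp$hour_bin, seq(0, 22, 2))
  expect_equal(comp$mean_val, rep(2, 12))
  expect_equal(comp$se, rep(0, 12))
  # equal-n partition identity: weighted mean of bins = overall mean
  set.seed(42)
  q15$mean_val <- rnorm(96)
  comp <- diel_composite(q15, mean_val)
  expect_equal(sum(comp$mean_val * comp$n_obs) / sum(comp$n_obs),
               mean(q15$mean_val))
  # empty input stays empty
  expect_equal(nrow(diel_composite(q15[0, ], mean_val)), 0)
})

test_that("synthetic diel pCO2 cycle puts peak uptake in the afternoon bins", {
  cfg <- scenario_config("macroalgae-summer", n_days = 2, seed = 9)
  rec <- simulate_campaign(cfg)
  daily15 <- compute_fluxes(dplyr::rename(rec$gas, qc_flag = flag),
                            rec$env) %>%
    dplyr::filter(gas == "CO2") %>%
    resample_mean(flux_mg_m2_d, width_s = 900)
  comp <- diel_composite(daily15, mean_val)
  argmin <- comp$hour_bin[which.min(comp$mean_val)]
  expect_true(argmin %in% c(12, 14, 16))
})

test_that("daily integration applies the coverage threshold", {
  start <- as.POSIXct("2020-07-06", tz = "UTC")
  full <- tibble::tibble(interval = start + 900 * (0:95), mean_val = 2)
  d <- daily_net_flux(full)
  expect_equal(d$mean_flux, 2)
  expect_equal(d$se_flux, 0)
  expect_equal(d$n_intervals, 96L)
  # 40% coverage at the default 50% threshold -> missing with reason
  partial <- full[1:38, ]
  dp <- daily_net_flux(partial)
  expect_true(is.na(dp$mean_flux))
  expect_equal(dp$reason, "insufficient_coverage")
  # partition invariance: pooling chunked equal-n interval means matches
  set.seed(1)
  full$mean_val <- rnorm(96)
  expect_equal(daily_net_flux(full)$mean_flux, mean(full$mean_val))
})

test_that("environment joins by nearest time with a gap limit", {
  start <- as.POSIXct("2020-07-06", tz = "UTC")
  env <- make_env_constant(start, n_min = 60)
  env$twater_c <- seq_len(60)  # minute index as temperature
  rec <- tibble::tibble(timestamp = start + c(0, 29, 31, 3600 + 1800))
  joined <- join_environment(rec, env, max_gap_s = 900)
  expect_equal(joined$twater_c, c(1, 1, 2, NA))
})

test_that("the pipeline is deterministic and round-trips through CSV", {
  cfg <- scenario_config("macroalgae-summer", n_days = 1, seed = 21)
  dir <- withr::local_tempdir()
  simulate_campaign(cfg, out_dir = dir)
  sim2 <- simulate_campaign(cfg)
  gas_rt <- read_gas_stream(file.path(dir, "gas.csv"))
  env_rt <- read_env_series(file.path(dir, "env.csv"))
  expect_equal(gas_rt$xch4_ppm, sim2$gas$xch4_ppm)
  expect_equal(gas_rt$timestamp, sim2$gas$timestamp)
  d1 <- daily_fluxes(gas_rt, env_rt)
  d2 <- daily_fluxes(dplyr::rename(sim2$gas, qc_flag = flag), sim2$env)
  expect_identical(d1$mean_flux, d2$mean_flux)
  out_csv <- file.path(dir, "daily.csv")
  flux_pipeline(file.path(dir, "gas.csv"), file.path(dir, "env.csv"),
                out = out_csv)
  expect_true(file.exists(out_csv))
  back <- readr::read_csv(out_csv, show_col_types = FALSE)
  expect_equal(back$mean_flux_mg_m2_d, d1$mean_flux)
})
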