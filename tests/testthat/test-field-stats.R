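test_that("summary-statistics ANOVA equals raw-data ANOVA", {
  # identical groups: no between-group variance
  same <- tibble::tibble(label = c("a", "b"), mean = 5, sd = 1, n = c(10, 10))
  expect_equal(anova_from_summaries(same)$f_statistic, 0)

  # against stats::oneway.test on raw data with exactly these moments
  set.seed(101)
  for (i in 1:10) {
    g <- random_group_summaries(sample(2:5, 1))
    raw <- purrr::pmap_dfr(g, function(label, mean, sd, n) {
      tibble::tibble(label = label, y = raw_from_summary(mean, sd, n))
    })
    ref <- stats::oneway.test(y ~ label, data = raw, var.equal = TRUE)
    fit <- anova_from_summaries(g)
    expect_equal(fit$f_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(fit$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(fit$df_within, unname(ref$parameter[2]))
  }

  # degenerate: zero within-group variance with distinct means
  degen <- tibble::tibble(label = c("a", "b"), mean = c(1, 2), sd = 0, n = 5)
  fit <- anova_from_summaries(degen)
  expect_true(fit$f_infinite)
  expect_identical(fit$f_statistic, Inf)

  expect_error(anova_from_summaries(same[1, ]), "two groups")
  expect_error(
    anova_from_summaries(tibble::tibble(label = c("a", "b"), mean = 1,
                                        sd = 1, n = c(1, 5))),
    "n >= 2"
  )
})

test_that("tidy and glance expose the ANOVA table", {
  g <- random_group_summaries(3)
  fit <- anova_from_summaries(g)
  td <- tidy(fit)
  expect_equal(td$term, c("between", "within"))
  expect_equal(td$meansq, c(fit$msb, fit$mse))
  gl <- glance(fit)
  expect_equal(gl$n_obs, sum(g$n))
  expect_equal(gl$statistic, fit$f_statistic)
})

test_that("summary-statistics Tukey equals raw-data TukeyHSD", {
  set.seed(202)
  for (i in 1:10) {
    g <- random_group_summaries(3)
    raw <- purrr::pmap_dfr(g, function(label, mean, sd, n) {
      tibble::tibble(label = label, y = raw_from_summary(mean, sd, n))
    })
    ref <- stats::TukeyHSD(stats::aov(y ~ label, data = raw))$label
    ours <- tukey_hsd_from_summaries(g)
    # TukeyHSD orders pairs as later-minus-earlier level
    key <- paste(ours$group_b, ours$group_a, sep = "-")
    ref <- ref[key, , drop = FALSE]
    expect_equal(ours$difference, unname(ref[, "diff"]), tolerance = 1e-10)
    expect_equal(ours$ci_low, unname(ref[, "lwr"]), tolerance = 1e-8)
    expect_equal(ours$ci_high, unname(ref[, "upr"]), tolerance = 1e-8)
    expect_equal(ours$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  }
})

test_that("two-group Tukey collapses to the pooled-t interval", {
  g <- tibble::tibble(label = c("a", "b"), mean = c(10, 12),
                      sd = c(2, 2.5), n = c(12, 15))
  ours <- tukey_hsd_from_summaries(g, alpha = 0.05)
  mse <- (11 * 4 + 14 * 6.25) / 25
  tq <- stats::qt(0.975, 25)
  hw <- tq * sqrt(mse * (1 / 12 + 1 / 15))
  expect_equal(ours$ci_high - ours$difference, hw, tolerance = 1e-6)
  expect_error(tukey_hsd_from_summaries(g, alpha = 1.2), "alpha")
})

test_that("Tukey intervals widen monotonically as alpha decreases", {
  g <- random_group_summaries(4)
  widths <- vapply(c(0.2, 0.1, 0.05, 0.01), function(a) {
    r <- tukey_hsd_from_summaries(g, alpha = a)
    r$ci_high[1] - r$ci_low[1]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  # interval symmetric about the difference
  r <- tukey_hsd_from_summaries(g)
  expect_equal(r$ci_high - r$difference, r$difference - r$ci_low)
})

test_that("oxygen penetration depth applies threshold and persistence", {
  depths <- seq(0, 4000, 100)
  # monotone profile crossing 1 uM at 2300 um
  conc <- ifelse(depths < 2300, 24 - depths / 100, 0.5)
  prof <- tibble::tibble(depth_um = depths, o2_um = conc)
  expect_equal(oxygen_penetration_depth(prof), 2300)

  # never below threshold
  oxic <- tibble::tibble(depth_um = depths, o2_um = 50)
  res <- oxygen_penetration_depth(oxic)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "not reached")

  # a single spurious sub-threshold dip is skipped (persistence > 1),
  # verified against a brute-force scan
  noisy <- conc
  noisy[8] <- 0.2   # one-point dip at 700 um
  profn <- tibble::tibble(depth_um = depths, o2_um = noisy)
  expect_equal(oxygen_penetration_depth(profn, persistence = 3), 2300)
  brute <- function(o2, d, thr, per) {
    for (i in seq_along(o2)) {
      w <- i:min(i + per - 1, length(o2))
      if (all(o2[w] < thr) && (length(w) == per || max(w) == length(o2))) {
        return(d[i])
      }
    }
    NA_real_
  }
  expect_equal(oxygen_penetration_depth(profn, persistence = 3),
               brute(noisy, depths, 1, 3))
  expect_equal(oxygen_penetration_depth(profn, persistence = 1), 700)

  # invariant to appending deeper all-below-threshold points
  deeper <- dplyr::bind_rows(profn,
                             tibble::tibble(depth_um = seq(4100, 5000, 100),
                                            o2_um = 0.1))
  expect_equal(oxygen_penetration_depth(deeper), 2300)

  expect_error(
    oxygen_penetration_depth(tibble::tibble(depth_um = 1, o2_um = NA_real_)),
    "usable"
  )
})
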