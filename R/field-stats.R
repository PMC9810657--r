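#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way ANOVA table from per-group means, standard
#' deviations and sample sizes alone.  With the grand mean weighted by n,
#' the between-group mean square is `sum(n_i (m_i - grand)^2) / (k - 1)`
#' and the within-group mean square `sum((n_i - 1) sd_i^2) / (N - k)`;
#' `F = MSB / MSE`.  The result is identical to a raw-data ANOVA on any
#' dataset having exactly these moments.
#'
#' @param groups Tibble with columns `label`, `mean`, `sd`, `n`
#'   (`n >= 2` each; at least two groups).
#' @return An object of class `summary_anova`: a list with `f_statistic`,
#'   `df_between`, `df_within`, `msb`, `mse`, `p_value`, `grand_mean`,
#'   `groups`, and `f_infinite` (TRUE when MSE is zero with nonzero MSB).
#' @examples
#' g <- tibble::tibble(label = c("a", "b"), mean = c(1, 2),
#'                     sd = c(0.5, 0.5), n = c(10, 12))
#' anova_from_summaries(g)
#' @export
anova_from_summaries <- function(groups) {
  groups <- validate_groups(groups)
  k <- nrow(groups)
  n_tot <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / n_tot
  df_b <- k - 1L
  df_w <- n_tot - k
  msb <- sum(groups$n * (groups$mean - grand)^2) / df_b
  mse <- sum((groups$n - 1) * groups$sd^2) / df_w
  f_inf <- mse == 0 && msb > 0
  f <- if (f_inf) Inf else if (mse == 0) NaN else msb / mse
  p <- if (is.finite(f)) stats::pf(f, df_b, df_w, lower.tail = FALSE)
       else if (is.infinite(f)) 0 else NaN
  structure(
    list(
      f_statistic = f, df_between = df_b, df_within = df_w,
      msb = msb, mse = mse, p_value = p, grand_mean = grand,
      groups = groups, f_infinite = f_inf
    ),
    class = "summary_anova"
  )
}

validate_groups <- function(groups) {
  needed <- c("label", "mean", "sd", "n")
  missing_cols <- setdiff(needed, names(groups))
  if (length(missing_cols)) {
    abort(sprintf("`groups` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(groups) < 2) {
    abort("At least two groups are required.")
  }
  if (any(groups$n < 2)) {
    abort("Every group needs n >= 2.")
  }
  if (any(groups$sd < 0)) {
    abort("Standard deviations must be non-negative.")
  }
  if (anyDuplicated(groups$label)) {
    abort("Group labels must be unique.")
  }
  as_tibble(groups)
}

#' @export
print.summary_anova <- function(x, ...) {
  cat("One-way ANOVA from group summaries\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat(sprintf("  MSB = %.6g, MSE = %.6g\n", x$msb, x$mse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a summary-statistics ANOVA
#'
#' @param x A `summary_anova` object.
#' @param ... Unused.
#' @return `tidy()`: one row per ANOVA term (between / within) with
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`.  `glance()`: a
#'   one-row tibble with the model-level statistics.
#' @method tidy summary_anova
#' @export
tidy.summary_anova <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$msb * x$df_between, x$mse * x$df_within),
    meansq = c(x$msb, x$mse),
    statistic = c(x$f_statistic, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @rdname tidy.summary_anova
#' @method glance summary_anova
#' @export
glance.summary_anova <- function(x, ...) {
  tibble(
    statistic = x$f_statistic, p.value = x$p_value,
    df_between = x$df_between, df_within = x$df_within,
    mse = x$mse, n_groups = nrow(x$groups), n_obs = sum(x$groups$n)
  )
}

#' Tukey HSD simultaneous confidence intervals from group summaries
#'
#' Computes Tukey honestly-significant-difference simultaneous confidence
#' intervals for all pairwise mean differences using only per-group
#' summary statistics.  For the pair (a, b), taken in the declared input
#' order, the difference is `mean_b - mean_a`, its standard error
#' `sqrt(MSE/2 * (1/n_a + 1/n_b))`, and the interval half-width is the
#' studentized-range quantile `q(1 - alpha; k, N - k)` times that SE.
#' The declared input order defines the sign of each difference.
#'
#' @inheritParams anova_from_summaries
#' @param alpha Simultaneous error rate (default 0.05).
#' @return A tibble of class `coastalghg_tukey`, one row per pair:
#'   `group_a`, `group_b`, `difference`, `ci_low`, `ci_high`, `se`,
#'   `q_critical`, `p_adj`, `alpha`, `df_within`.
#' @examples
#' g <- tibble::tibble(
#'   label = c("macroalgae", "open_water_1", "open_water_2"),
#'   mean = c(56.69, 50.41, 49.73), sd = c(0.76, 1.48, 2.48),
#'   n = c(70, 105, 119)
#' )
#' tukey_hsd_from_summaries(g)
#' @export
tukey_hsd_from_summaries <- function(groups, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  aov_fit <- anova_from_summaries(groups)
  groups <- aov_fit$groups
  k <- nrow(groups)
  df_w <- aov_fit$df_within
  qcrit <- stats::qtukey(1 - alpha, nmeans = k, df = df_w)
  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]
  j <- pairs[2, ]
  se <- sqrt(aov_fit$mse / 2 * (1 / groups$n[i] + 1 / groups$n[j]))
  diff <- groups$mean[j] - groups$mean[i]
  out <- tibble(
    group_a = groups$label[i],
    group_b = groups$label[j],
    difference = diff,
    ci_low = diff - qcrit * se,
    ci_high = diff + qcrit * se,
    se = se,
    q_critical = qcrit,
    p_adj = stats::ptukey(abs(diff) / se, nmeans = k, df = df_w,
                          lower.tail = FALSE),
    alpha = alpha,
    df_within = df_w
  )
  class(out) <- c("coastalghg_tukey", class(out))
  out
}

#' Oxygen penetration depth from a sediment microprofile
#'
#' The oxygen penetration depth (OPD) is the shallowest depth at or below
#' the sediment-water interface (depth 0, positive downward) where the O2
#' concentration falls below the threshold (1 uM by default) and stays
#' below it.  To be robust against single-point microsensor noise, the
#' sub-threshold condition must persist for at least `persistence`
#' consecutive measured points (or reach the end of the profile).
#'
#' @param profile Tibble with strictly increasing `depth_um` and
#'   `o2_um` (missing concentrations are ignored).
#' @param threshold Concentration threshold, uM (default 1).
#' @param persistence Number of consecutive sub-threshold points required
#'   (default 3, i.e. 300 um at 100-um resolution).
#' @return The penetration depth in um, or `NA` with attribute
#'   `reason = "not reached"` when the profile never stays below the
#'   threshold.
#' @examples
#' prof <- tibble::tibble(depth_um = seq(0, 3000, 100),
#'                        o2_um = pmax(250 - 0.11 * seq(0, 3000, 100), 0))
#' oxygen_penetration_depth(prof)
#' @export
oxygen_penetration_depth <- function(profile, threshold = 1, persistence = 3) {
  needed <- c("depth_um", "o2_um")
  if (!all(needed %in% names(profile))) {
    abort("`profile` needs columns depth_um and o2_um.")
  }
  prof <- profile %>%
    filter(!is.na(o2_um), depth_um >= 0) %>%
    arrange(depth_um)
  if (!nrow(prof)) {
    abort("Profile has no usable (non-missing, depth >= 0) points.")
  }
  if (any(diff(prof$depth_um) <= 0)) {
    abort("Depths must be strictly increasing.")
  }
  below <- prof$o2_um < threshold
  r <- rle(below)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ok_run <- r$values & (r$lengths >= persistence | run_end == nrow(prof))
  if (!any(ok_run)) {
    return(structure(NA_real_, reason = "not reached"))
  }
  prof$depth_um[run_start[which(ok_run)[1]]]
}
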