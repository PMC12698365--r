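# shared fixtures: all synthetic, built in code at test time

tiny_cohort <- function(n = 40, seed = 7, ...) {
  simulate_cohort(cohort_params(n = n, seed = seed, ...))
}

# hand-built void records for one child; hours_day1 are clock hours on
# day 1, fvu_hour the day-2 first-void clock hour
fixture_voids <- function(child = "kid1",
                          hours_day1 = c(9, 12, 15.5, 20),
                          fvu_hour = 6.5,
                          vol = NULL, cre = NULL, na = 100, k = 40,
                          sg = 1.02) {
  origin <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")
  hours <- c(hours_day1, 24 + fvu_hour)
  m <- length(hours)
  data.frame(
    child_id = child,
    timestamp = origin + hours * 3600,
    volume_ml = if (is.null(vol)) rep(150, m) else rep_len(vol, m),
    cre_mg_dl = if (is.null(cre)) rep(70, m) else rep_len(cre, m),
    na_meq_l = rep_len(na, m),
    k_meq_l = rep_len(k, m),
    sg = rep_len(sg, m),
    stringsAsFactors = FALSE
  )
}

# explicit-summation Bland-Altman oracle (independent of the package's
# lm-based implementation)
ba_oracle <- function(est, meas) {
  n <- length(est)
  d <- est - meas
  a <- (est + meas) / 2
  md <- sum(d) / n
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  sxx <- sum((a - mean(a))^2)
  sxy <- sum((a - mean(a)) * (d - md))
  slope <- sxy / sxx
  ic <- md - slope * mean(a)
  sse <- sum((d - ic - slope * a)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  list(
    mean_diff = md, sd_diff = sdd,
    ci_low = md - stats::qt(0.975, n - 1) * sdd / sqrt(n),
    ci_high = md + stats::qt(0.975, n - 1) * sdd / sqrt(n),
    loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
    trend_slope = slope,
    trend_p = 2 * stats::pt(-abs(slope / se), n - 2)
  )
}
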