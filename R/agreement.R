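#' Bland-Altman method agreement with trend-bias decomposition
#'
#' Compares an estimated against a measured series pairwise. The
#' difference is oriented estimated - measured (flip with
#' \code{orientation}); the abscissa is the pair mean. Reports the fixed
#' error (mean difference with Student-t 95% CI on n - 1 df), the 95%
#' limits of agreement (mean difference +/- 1.96 SD of differences, the
#' conventional normal-quantile multiplier), and the proportional error:
#' the OLS slope of difference on mean with its two-sided t-test p-value
#' (n - 2 df).
#'
#' @param estimated,measured equal-length numeric series (same units),
#'   paired by subject.
#' @param orientation "estimated-measured" (default) or
#'   "measured-estimated".
#' @param conf confidence level for the CI of the mean difference.
#' @return object of class \code{bland_altman}: \code{n, mean_diff,
#'   sd_diff, ci_low, ci_high, loa_low, loa_high, trend_slope, trend_p}
#'   and the per-pair \code{data} (mean, difference). When the pair means
#'   have zero variance the trend is undefined and reported NA with a
#'   warning.
#' @examples
#' ba <- bland_altman(c(380, 490, 620), c(400, 500, 600))
#' ba$trend_slope  # ~0.183
#' @export
bland_altman <- function(estimated, measured,
                         orientation = c("estimated-measured",
                                         "measured-estimated"),
                         conf = 0.95) {
  orientation <- match.arg(orientation)
  estimated <- as.numeric(estimated)
  measured <- as.numeric(measured)
  if (length(estimated) != length(measured)) {
    stop("bland_altman: series must have equal length", call. = FALSE)
  }
  keep <- is.finite(estimated) & is.finite(measured)
  estimated <- estimated[keep]
  measured <- measured[keep]
  n <- length(estimated)
  if (n < 3) stop("bland_altman: need at least 3 pairs", call. = FALSE)
  d <- if (orientation == "estimated-measured") estimated - measured
       else measured - estimated
  a <- (estimated + measured) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se <- sdd / sqrt(n)
  if (stats::var(a) > 0) {
    fit <- stats::lm(d ~ a)
    sl <- unname(stats::coef(fit)[2])
    pv <- summary(fit)$coefficients[2, 4]
  } else {
    warning("bland_altman: zero variance of pair means; trend undefined",
            call. = FALSE)
    sl <- NA_real_
    pv <- NA_real_
  }
  structure(list(
    n = n,
    mean_diff = md,
    sd_diff = sdd,
    ci_low = md - tq * se,
    ci_high = md + tq * se,
    loa_low = md - 1.96 * sdd,
    loa_high = md + 1.96 * sdd,
    trend_slope = sl,
    trend_p = pv,
    orientation = orientation,
    conf = conf,
    data = data.frame(mean = a, difference = d)
  ), class = "bland_altman")
}

#' @export
#' @method print bland_altman
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (", x$orientation, ", n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  mean difference: %.2f (%g%% CI %.2f to %.2f)\n",
              x$mean_diff, 100 * x$conf, x$ci_low, x$ci_high))
  cat(sprintf("  95%% LOA: %.2f to %.2f\n", x$loa_low, x$loa_high))
  if (is.na(x$trend_slope)) {
    cat("  trend bias: undefined (zero variance of means)\n")
  } else {
    cat(sprintf("  trend bias: %.3f (p = %.3g)\n", x$trend_slope, x$trend_p))
  }
  invisible(x)
}

#' Plot-ready representation of a Bland-Altman result
#'
#' Emits the per-pair points plus the horizontal reference lines (mean
#' difference, both limits of agreement) and the fitted trend line
#' evaluated at the extremes of the mean axis.
#'
#' @param result a \code{\link{bland_altman}} object.
#' @return list with \code{points} (n rows), \code{lines} (mean/LOA
#'   levels) and \code{trend} (two endpoint rows, NULL if undefined).
#' @export
ba_plot_data <- function(result) {
  stopifnot(inherits(result, "bland_altman"))
  rng <- range(result$data$mean)
  trend <- if (is.na(result$trend_slope)) NULL else {
    ic <- result$mean_diff - result$trend_slope * mean(result$data$mean)
    data.frame(mean = rng, difference = ic + result$trend_slope * rng)
  }
  list(
    points = result$data,
    lines = data.frame(
      what = c("mean_diff", "loa_low", "loa_high"),
      level = c(result$mean_diff, result$loa_low, result$loa_high)
    ),
    trend = trend
  )
}

#' @export
plot.bland_altman <- function(x, ...,
                              xlab = "Mean of estimated and measured",
                              ylab = "Difference (estimated - measured)",
                              main = "Bland-Altman plot") {
  pd <- ba_plot_data(x)
  plot(pd$points$mean, pd$points$difference, xlab = xlab, ylab = ylab,
       main = main, pch = 19, col = "grey30", ...)
  graphics::abline(h = x$mean_diff, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  if (!is.null(pd$trend)) {
    graphics::lines(pd$trend$mean, pd$trend$difference, col = "red3")
  }
  invisible(x)
}

#' Agreement summary for a battery of methods
#'
#' Runs \code{\link{bland_altman}} for every method in a long estimates
#' table against measured excretion, returning one row per method with
#' the standard agreement columns (mean difference, its CI, trend slope
#' and p, LOA). Methods with too few valid pairs get NA rows.
#'
#' @param estimates long data.frame \code{child_id, method,
#'   cre24_pred_mg_day} (as from \code{\link{cre_battery}}).
#' @param measured data.frame \code{child_id} + measured column.
#' @param measured_col name of the measured column.
#' @return data.frame, one row per method.
#' @export
battery_agreement <- function(estimates, measured,
                              measured_col = "cre24_mg_day") {
  .need_cols(estimates, c("child_id", "method", "cre24_pred_mg_day"),
             "battery_agreement")
  .need_cols(measured, c("child_id", measured_col), "battery_agreement")
  methods <- unique(estimates$method)
  rows <- lapply(methods, function(m) {
    e <- estimates[estimates$method == m, , drop = FALSE]
    y <- measured[[measured_col]][match(e$child_id, measured$child_id)]
    ba <- tryCatch(suppressWarnings(bland_altman(e$cre24_pred_mg_day, y)),
                   error = function(err) NULL)
    note <- if (!is.null(e$note[1]) && nzchar(e$note[1])) e$note[1] else ""
    if (is.null(ba)) {
      data.frame(method = m, n = sum(is.finite(e$cre24_pred_mg_day) &
                                       is.finite(y)),
                 mean_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 trend_slope = NA_real_, trend_p = NA_real_,
                 loa_low = NA_real_, loa_high = NA_real_,
                 note = if (nzchar(note)) note else "not computable",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(method = m, n = ba$n, mean_diff = ba$mean_diff,
                 ci_low = ba$ci_low, ci_high = ba$ci_high,
                 trend_slope = ba$trend_slope, trend_p = ba$trend_p,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 note = note, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
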