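# Consensus CGM metric suite.
#
# Metrics follow the consensus clinical targets for CGM reporting: percent
# wear time, mean glucose, percent time in range (TIR, 70-180 mg/dL
# inclusive), time below range (<70 and <54 mg/dL) and time above range
# (>180 and >250 mg/dL).  The boundary conventions make the three top-level
# bands (<70, 70-180, >180) an exact partition of the glucose axis, so
# tbr70 + tir + tar180 = 100 whenever at least one sample exists.
# Percentages weight samples equally (CGM sampling is nominally uniform at
# 5 minutes); there is no duration weighting.

#' Define a review period
#'
#' A half-open interval `[start, end)`; samples at `end` belong to the next
#' period.  The default clinical cadence is 14 days.
#'
#' @param start POSIXct period start.
#' @param end POSIXct period end, or `NULL` for `start + days`.
#' @param days period length in days when `end` is `NULL` (default 14).
#' @return object of class `review_period`.
#' @export
review_period <- function(start, end = NULL, days = 14) {
  if (is.null(end)) end <- start + days * 86400
  if (!(end > start)) stop("review_period: end must follow start")
  structure(list(start = start, end = end), class = "review_period")
}

#' @export
print.review_period <- function(x, ...) {
  cat(sprintf("<review_period> [%s, %s)\n", format(x$start), format(x$end)))
  invisible(x)
}

.period_samples <- function(trace, period) {
  s <- trace$samples
  s[s$timestamp >= period$start & s$timestamp < period$end, , drop = FALSE]
}

.period_minutes <- function(period) {
  as.numeric(difftime(period$end, period$start, units = "mins"))
}

#' Percent CGM wear time
#'
#' The fraction of expected samples actually observed:
#' `100 * observed / (period_minutes / sampling_interval)`, capped at 100.
#' A fully worn day at the nominal 5-minute cadence has 288 samples.
#'
#' @param trace a [glucose_trace()].
#' @param period a [review_period()].
#' @param sampling_interval_min nominal sampling interval in minutes
#'   (default 5).
#' @return percent in `[0, 100]`.
#' @export
cgm_wear_percent <- function(trace, period, sampling_interval_min = 5) {
  stopifnot(sampling_interval_min > 0)
  expected <- .period_minutes(period) / sampling_interval_min
  min(100, 100 * nrow(.period_samples(trace, period)) / expected)
}

#' Mean glucose over a review period
#'
#' Arithmetic mean of the raw sample values in the period; `NA` (never
#' zero) when the period holds no samples.
#'
#' @inheritParams cgm_wear_percent
#' @return mg/dL, or `NA_real_`.
#' @export
mean_glucose <- function(trace, period) {
  s <- .period_samples(trace, period)
  if (nrow(s) == 0) return(NA_real_)
  mean(s$glucose)
}

#' Define a glucose band
#'
#' @param lower,upper bounds in mg/dL; `-Inf`/`Inf` for unbounded sides.
#' @param lower_inclusive,upper_inclusive whether each bound is attained.
#' @return object of class `glucose_band`.
#' @export
glucose_band <- function(lower = -Inf, upper = Inf,
                         lower_inclusive = TRUE, upper_inclusive = TRUE) {
  if (is.finite(lower) && is.finite(upper) && !(lower < upper))
    stop("glucose_band: lower must be below upper")
  structure(list(lower = lower, upper = upper,
                 lower_inclusive = lower_inclusive,
                 upper_inclusive = upper_inclusive),
            class = "glucose_band")
}

#' @rdname glucose_band
#' @export
band_tir <- function() glucose_band(70, 180, TRUE, TRUE)
#' @rdname glucose_band
#' @export
band_tbr70 <- function() glucose_band(upper = 70, upper_inclusive = FALSE)
#' @rdname glucose_band
#' @export
band_tbr54 <- function() glucose_band(upper = 54, upper_inclusive = FALSE)
#' @rdname glucose_band
#' @export
band_tar180 <- function() glucose_band(lower = 180, lower_inclusive = FALSE)
#' @rdname glucose_band
#' @export
band_tar250 <- function() glucose_band(lower = 250, lower_inclusive = FALSE)

#' Test glucose values against a band
#'
#' @param band a [glucose_band()].
#' @param x numeric glucose values.
#' @return logical vector.
#' @export
band_contains <- function(band, x) {
  lo <- if (band$lower_inclusive) x >= band$lower else x > band$lower
  hi <- if (band$upper_inclusive) x <= band$upper else x < band$upper
  lo & hi
}

#' Percent of samples in a glucose band
#'
#' `100 * (samples satisfying the band) / (samples in period)`; samples are
#' weighted equally.  `NA` when the period holds no samples.
#'
#' @inheritParams cgm_wear_percent
#' @param band a [glucose_band()].
#' @return percent in `[0, 100]`, or `NA_real_`.
#' @export
percent_time_in_band <- function(trace, period, band) {
  s <- .period_samples(trace, period)
  if (nrow(s) == 0) return(NA_real_)
  100 * sum(band_contains(band, s$glucose)) / nrow(s)
}

#' CGM summary for one review period
#'
#' Computes the full consensus metric row: wear percent, mean glucose, TIR
#' (70-180 inclusive), TBR (<70, <54), TAR (>180, >250), and the change in
#' TIR from the previous period in percentage points (absent without a
#' previous summary).
#'
#' @inheritParams cgm_wear_percent
#' @param previous the previous period's `cgm_summary`, or `NULL`.
#' @return object of class `cgm_summary`.
#' @export
cgm_summary <- function(trace, period, previous = NULL,
                        sampling_interval_min = 5) {
  tir <- percent_time_in_band(trace, period, band_tir())
  out <- structure(list(
    patient_id = trace$patient_id,
    period = period,
    wear_pct = cgm_wear_percent(trace, period, sampling_interval_min),
    mean_glucose = mean_glucose(trace, period),
    tir_pct = tir,
    tir_change_pp = if (!is.null(previous) && !is.na(previous$tir_pct) &&
                          !is.na(tir)) tir - previous$tir_pct else NA_real_,
    tbr70_pct = percent_time_in_band(trace, period, band_tbr70()),
    tbr54_pct = percent_time_in_band(trace, period, band_tbr54()),
    tar180_pct = percent_time_in_band(trace, period, band_tar180()),
    tar250_pct = percent_time_in_band(trace, period, band_tar250())),
    class = "cgm_summary")
  out
}

#' @export
print.cgm_summary <- function(x, ...) {
  cat(sprintf("<cgm_summary> patient %s, [%s, %s)\n", x$patient_id,
              format(x$period$start), format(x$period$end)))
  cat(sprintf("  wear %.1f%%  mean %.1f mg/dL  TIR %.1f%% (change %s pp)\n",
              x$wear_pct, x$mean_glucose, x$tir_pct,
              if (is.na(x$tir_change_pp)) "--"
              else sprintf("%+.1f", x$tir_change_pp)))
  cat(sprintf("  TBR<70 %.1f%%  TBR<54 %.1f%%  TAR>180 %.1f%%  TAR>250 %.1f%%\n",
              x$tbr70_pct, x$tbr54_pct, x$tar180_pct, x$tar250_pct))
  invisible(x)
}
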