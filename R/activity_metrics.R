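# Physical-activity metrics.
#
# Tracker wear time is inferred from heart-rate data (a minute counts as
# worn iff at least one valid heart-rate sample falls in it).  Step and MET
# minutes are aggregated into fixed epochs (default 15 minutes, anchored at
# local midnight, half-open [start, start+epoch)) and each epoch's mean MET
# classifies its intensity as sedentary / active / highly_active.  MVPA
# (moderate-to-vigorous physical activity) is counted in whole
# highly-active epochs; the daily exercise guideline for youth is at least
# 60 MVPA minutes.

#' Percent tracker wear time from heart-rate data
#'
#' A minute is worn iff it holds at least one valid heart-rate sample;
#' returns `100 * worn minutes / total minutes` over the period.
#'
#' @param heart_rate data frame `timestamp`, `bpm` (cleaned).
#' @param period a [review_period()].
#' @return percent in `[0, 100]`.
#' @export
hr_wear_percent <- function(heart_rate, period) {
  total_min <- .period_minutes(period)
  if (total_min <= 0) stop("hr_wear_percent: zero-length period")
  ts <- heart_rate$timestamp
  ts <- ts[!is.na(ts) & ts >= period$start & ts < period$end]
  worn <- length(unique(as.numeric(floor_minute(ts))))
  min(100, 100 * worn / total_min)
}

#' Aggregate minute data into epoch summaries
#'
#' Epochs tile each calendar day as half-open intervals
#' `[start, start + epoch_minutes)` anchored at local midnight.  Epoch steps
#' are the sum of member step minutes; `mean_met` the mean of member MET
#' minutes (absent minutes excluded; `NA` when the epoch holds no MET
#' data).  Epochs with no step and no MET data are omitted.
#'
#' @param steps data frame `minute_start`, `steps`.
#' @param mets data frame `minute_start`, `met`.
#' @param epoch_minutes epoch length in minutes; must divide 1440
#'   (default 15).
#' @param met_cutpoints passed to [classify_epoch_intensity()].
#' @return data frame `start`, `duration_s`, `steps`, `mean_met`,
#'   `intensity` (one row per data-bearing epoch, time-ordered).
#' @export
aggregate_epochs <- function(steps, mets, epoch_minutes = 15,
                             met_cutpoints = c(1.5, 3)) {
  if (1440 %% epoch_minutes != 0)
    stop("epoch_minutes must divide 1440")
  esec <- epoch_minutes * 60
  ekey <- function(t) floor(as.numeric(t) / esec) * esec
  skey <- if (nrow(steps)) ekey(steps$minute_start) else numeric()
  mkey <- if (nrow(mets)) ekey(mets$minute_start) else numeric()
  keys <- sort(unique(c(skey, mkey)))
  if (length(keys) == 0)
    return(data.frame(start = .POSIXct(numeric(), tz = "UTC"),
                      duration_s = numeric(), steps = integer(),
                      mean_met = numeric(), intensity = character()))
  step_sum <- vapply(keys, function(k)
    sum(steps$steps[skey == k]), numeric(1))
  mean_met <- vapply(keys, function(k) {
    v <- mets$met[mkey == k]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  data.frame(start = .POSIXct(keys, tz = "UTC"),
             duration_s = esec,
             steps = as.integer(round(step_sum)),
             mean_met = mean_met,
             intensity = classify_epoch_intensity(mean_met, met_cutpoints),
             stringsAsFactors = FALSE)
}

#' Classify epoch intensity from mean METs
#'
#' `sedentary` below `met_low`, `active` in `[met_low, met_high)`,
#' `highly_active` at or above `met_high`.  The defaults (1.5, 3.0) use the
#' conventional 3-MET moderate-intensity floor, so highly-active epochs
#' operationalize MVPA.  `NA` mean MET yields `NA` intensity (the epoch is
#' excluded from MVPA).
#'
#' @param mean_met numeric vector of epoch mean METs.
#' @param met_cutpoints length-2 increasing cutpoints `(met_low, met_high)`.
#' @return character vector of intensities.
#' @export
classify_epoch_intensity <- function(mean_met, met_cutpoints = c(1.5, 3)) {
  stopifnot(length(met_cutpoints) == 2, met_cutpoints[1] < met_cutpoints[2])
  ifelse(is.na(mean_met), NA_character_,
         ifelse(mean_met < met_cutpoints[1], "sedentary",
                ifelse(mean_met < met_cutpoints[2], "active",
                       "highly_active")))
}

#' Daily activity metrics for one calendar day
#'
#' Total steps, MVPA minutes (highly-active epochs times the epoch length),
#' tracker wear percent from heart rate, and whether the daily exercise
#' guideline (default 60 MVPA minutes) was met.  A day with no data in any
#' stream returns all-absent metrics with `guideline_met = FALSE`.
#'
#' @param bundle an [activity_bundle()].
#' @param date `Date` (or midnight POSIXct) of the day, in standard time.
#' @param epoch_minutes epoch length in minutes (default 15).
#' @param met_cutpoints intensity cutpoints (default `c(1.5, 3)`).
#' @param guideline_minutes daily MVPA guideline in minutes (default 60).
#' @return one-row data frame `date`, `total_steps`, `mvpa_minutes`,
#'   `tracker_wear_pct`, `guideline_met`.
#' @export
daily_activity <- function(bundle, date, epoch_minutes = 15,
                           met_cutpoints = c(1.5, 3),
                           guideline_minutes = 60) {
  day_start <- if (inherits(date, "Date"))
    .POSIXct(as.numeric(date) * 86400, tz = "UTC") else floor_day(date)
  day <- review_period(day_start, day_start + 86400)
  sel <- function(df, col) df[!is.na(df[[col]]) & df[[col]] >= day$start &
                                df[[col]] < day$end, , drop = FALSE]
  st <- sel(bundle$steps, "minute_start")
  mt <- sel(bundle$mets, "minute_start")
  hr <- sel(bundle$heart_rate, "timestamp")
  if (nrow(st) == 0 && nrow(mt) == 0 && nrow(hr) == 0) {
    return(data.frame(date = as.Date(as.numeric(day_start) / 86400,
                                     origin = "1970-01-01"),
                      total_steps = NA_integer_, mvpa_minutes = NA_real_,
                      tracker_wear_pct = NA_real_, guideline_met = FALSE))
  }
  epochs <- aggregate_epochs(st, mt, epoch_minutes, met_cutpoints)
  mvpa <- sum(epochs$intensity == "highly_active", na.rm = TRUE) *
    epoch_minutes
  data.frame(
    date = as.Date(as.numeric(day_start) / 86400, origin = "1970-01-01"),
    total_steps = as.integer(sum(st$steps)),
    mvpa_minutes = mvpa,
    tracker_wear_pct = hr_wear_percent(hr, day),
    guideline_met = mvpa >= guideline_minutes)
}

#' Activity summary for one review period
#'
#' Aggregates [daily_activity()] over every day of the period: tracker wear
#' percent over the whole period, mean daily steps and MVPA minutes over
#' data-bearing days, percent of period days meeting the guideline (no-data
#' days count as not met), and the percent change in mean daily MVPA from
#' the previous period (absent without a previous summary or when the
#' previous mean was zero).
#'
#' @param bundle an [activity_bundle()].
#' @param period a [review_period()] (day-aligned).
#' @param previous the previous period's `activity_summary`, or `NULL`.
#' @inheritParams daily_activity
#' @return object of class `activity_summary`.
#' @export
activity_summary <- function(bundle, period, previous = NULL,
                             epoch_minutes = 15, met_cutpoints = c(1.5, 3),
                             guideline_minutes = 60) {
  day_starts <- seq(from = as.numeric(floor_day(period$start)),
                    to = as.numeric(period$end) - 1, by = 86400)
  days <- do.call(rbind, lapply(day_starts, function(d)
    daily_activity(bundle, .POSIXct(d, tz = "UTC"), epoch_minutes,
                   met_cutpoints, guideline_minutes)))
  has_data <- !is.na(days$mvpa_minutes)
  mean_mvpa <- if (any(has_data)) mean(days$mvpa_minutes[has_data])
  else NA_real_
  change <- NA_real_
  if (!is.null(previous) && !is.na(previous$mean_daily_mvpa_min) &&
      previous$mean_daily_mvpa_min > 0 && !is.na(mean_mvpa))
    change <- 100 * (mean_mvpa - previous$mean_daily_mvpa_min) /
      previous$mean_daily_mvpa_min
  structure(list(
    patient_id = bundle$patient_id,
    period = period,
    tracker_wear_pct = hr_wear_percent(bundle$heart_rate, period),
    mean_daily_steps = if (any(has_data))
      mean(days$total_steps[has_data]) else NA_real_,
    mean_daily_mvpa_min = mean_mvpa,
    pct_days_guideline_met = 100 * sum(days$guideline_met) / nrow(days),
    activity_change_pct = change,
    daily = days), class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("<activity_summary> patient %s, [%s, %s)\n", x$patient_id,
              format(x$period$start), format(x$period$end)))
  cat(sprintf("  tracker wear %.1f%%  steps/day %.0f  MVPA %.1f min/day\n",
              x$tracker_wear_pct,
              ifelse(is.na(x$mean_daily_steps), NaN, x$mean_daily_steps),
              ifelse(is.na(x$mean_daily_mvpa_min), NaN,
                     x$mean_daily_mvpa_min)))
  cat(sprintf("  guideline met on %.1f%% of days; change %s%%\n",
              x$pct_days_guideline_met,
              if (is.na(x$activity_change_pct)) "--"
              else sprintf("%+.1f", x$activity_change_pct)))
  invisible(x)
}
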