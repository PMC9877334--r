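# Synthetic patient simulator.
#
# Generates paired CGM + activity data with known ground truth so the whole
# pipeline (parsing, synchronization, metrics, flags, ranking) is testable
# without any device download.  Glucose follows a mean-reverting AR(1)
# process on the nominal 5-minute grid, clipped to [40, 400] mg/dL; during
# each structured exercise bout a deterministic linear decline at the
# configured rate replaces the stochastic path, so configured declines are
# recovered exactly by the flag detector.  Heart rate is emitted once per
# minute (resting around 70 bpm, elevated with bout intensity); steps and
# METs per minute follow the bout schedule over a sedentary background
# (background METs below the sedentary cutpoint).  Configured CGM-dropout
# and tracker-nonwear gaps are removed from the emitted streams and
# recorded in the ground truth.
#
# All randomness derives from one integer seed, split deterministically
# per channel, so identical configs yield byte-identical payloads.

#' Default structured-exercise schedule
#'
#' One 60-minute after-school bout (16:00) on every other day, alternating
#' walking and running, with a glucose decline of 6 mg/dL per 10 minutes
#' (36 mg/dL over the bout) for walking and 10 mg/dL per 10 minutes
#' (60 mg/dL, enough to trigger the rapid-drop flag) for running.
#'
#' @param days number of simulated days.
#' @return data frame of bout specifications.
#' @export
default_bout_schedule <- function(days) {
  if (days < 2) return(empty_bout_schedule())
  offs <- seq(1, days - 1, by = 2)
  running <- seq_along(offs) %% 2 == 0
  data.frame(
    day_offset = offs,
    start_time = "16:00",
    duration_min = 60,
    activity_type = ifelse(running, "running", "walking"),
    drop_rate = ifelse(running, 10, 6),
    met_level = ifelse(running, 8, 3.5),
    steps_per_min = ifelse(running, 160L, 105L))
}

#' @rdname default_bout_schedule
#' @export
empty_bout_schedule <- function() {
  data.frame(day_offset = integer(), start_time = character(),
             duration_min = numeric(), activity_type = character(),
             drop_rate = numeric(), met_level = numeric(),
             steps_per_min = integer())
}

#' Build a simulation configuration
#'
#' @param seed integer master seed; fixes all randomness.
#' @param days number of simulated days (default 14, one review period).
#' @param glucose_mean stationary mean glucose in mg/dL (default 150).
#' @param glucose_sd stationary glucose SD in mg/dL (default 40).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)` (default 0.95, per
#'   5-minute step).
#' @param bouts bout schedule data frame (`day_offset`, `start_time`
#'   `"HH:MM"`, `duration_min`, `activity_type`, `drop_rate` in mg/dL per
#'   10 min, `met_level`, `steps_per_min`); default
#'   [default_bout_schedule()].
#' @param cgm_dropout,tracker_nonwear gap data frames (`day_offset`,
#'   `start_time`, `duration_min`); default none.
#' @param patient_id id stamped on the outputs.
#' @param start_date first simulated day, `"YYYY-MM-DD"` (standard time).
#' @param std_offset_min standard-time offset in minutes.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(seed, days = 14, glucose_mean = 150,
                              glucose_sd = 40, ar_coefficient = 0.95,
                              bouts = default_bout_schedule(days),
                              cgm_dropout = NULL, tracker_nonwear = NULL,
                              patient_id = "SIM001",
                              start_date = "2024-03-04",
                              std_offset_min = 0) {
  stopifnot(days >= 1, glucose_sd >= 0,
            ar_coefficient >= 0, ar_coefficient < 1)
  if (is.null(bouts)) bouts <- empty_bout_schedule()
  if (is.null(cgm_dropout)) cgm_dropout <- .empty_gaps()
  if (is.null(tracker_nonwear)) tracker_nonwear <- .empty_gaps()
  cfg <- structure(list(
    seed = as.integer(seed), days = as.integer(days),
    glucose_mean = glucose_mean, glucose_sd = glucose_sd,
    ar_coefficient = ar_coefficient, bouts = bouts,
    cgm_dropout = cgm_dropout, tracker_nonwear = tracker_nonwear,
    patient_id = as.character(patient_id), start_date = start_date,
    std_offset_min = std_offset_min), class = "sim_config")
  iv <- .bout_intervals(cfg)
  if (nrow(iv) > 1) {
    iv <- iv[order(iv$start), ]
    if (any(utils::head(iv$end, -1) > utils::tail(iv$start, -1)))
      stop("simulation_config: overlapping bouts")
  }
  cfg
}

.empty_gaps <- function() {
  data.frame(day_offset = integer(), start_time = character(),
             duration_min = numeric())
}

.sim_origin <- function(config) {
  std_time(paste(config$start_date, "00:00:00"))
}

.resolve_clock <- function(config, day_offset, start_time) {
  hm <- strsplit(start_time, ":", fixed = TRUE)
  secs <- vapply(hm, function(p)
    as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60, numeric(1))
  .sim_origin(config) + day_offset * 86400 + secs
}

.bout_intervals <- function(config) {
  b <- config$bouts
  if (nrow(b) == 0)
    return(data.frame(start = .POSIXct(numeric(), tz = "UTC"),
                      end = .POSIXct(numeric(), tz = "UTC")))
  start <- .resolve_clock(config, b$day_offset, b$start_time)
  data.frame(start = start, end = start + b$duration_min * 60)
}

.resolve_gaps <- function(config, gaps) {
  if (nrow(gaps) == 0)
    return(data.frame(start = .POSIXct(numeric(), tz = "UTC"),
                      duration_min = numeric()))
  data.frame(start = .resolve_clock(config, gaps$day_offset,
                                    gaps$start_time),
             duration_min = gaps$duration_min)
}

# Deterministic per-channel seed split from the master seed.
.channel_seed <- function(seed, channel) {
  offsets <- c(glucose = 104729, heart_rate = 224737, steps = 350377,
               mets = 479909)
  (abs(seed) + offsets[[channel]]) %% 2147483647L
}

#' Remove samples falling inside configured gaps
#'
#' Every record whose timestamp lies in a half-open gap
#' `[start, start + duration)` is removed; all others are untouched.
#'
#' @param records data frame with a timestamp column.
#' @param gaps data frame `start` (POSIXct), `duration_min`.
#' @param time_col timestamp column name.
#' @return the reduced data frame.
#' @export
inject_missingness <- function(records, gaps, time_col = "timestamp") {
  if (nrow(gaps) == 0 || nrow(records) == 0) return(records)
  ts <- records[[time_col]]
  drop <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(gaps)))
    drop <- drop | (ts >= gaps$start[i] &
                      ts < gaps$start[i] + gaps$duration_min[i] * 60)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate one patient
#'
#' Generates the CGM trace, the activity bundle and the ground truth for
#' one patient under a [simulation_config()].  Emitted objects serialize to
#' exactly the package's CGM CSV and activity JSON dialects (see
#' [write_simulated_patient()]) and parse back cleanly.
#'
#' @param config a [simulation_config()].
#' @return list with `trace` ([glucose_trace()]), `bundle`
#'   ([activity_bundle()]), `ground_truth` (per-bout true drop and minimum
#'   glucose; per-day true steps and MVPA minutes; injected gaps) and
#'   `config`.
#' @export
simulate_patient <- function(config) {
  origin <- .sim_origin(config)
  n_cgm <- config$days * 288L
  cgm_times <- origin + (seq_len(n_cgm) - 1) * 300
  bouts <- .bout_intervals(config)

  # glucose: AR(1) outside bouts; deterministic linear decline inside
  set.seed(.channel_seed(config$seed, "glucose"))
  phi <- config$ar_coefficient
  innov_sd <- config$glucose_sd * sqrt(1 - phi^2)
  innov <- stats::rnorm(n_cgm, 0, innov_sd)
  glucose <- numeric(n_cgm)
  x <- config$glucose_mean
  bout_idx <- rep(0L, n_cgm)
  for (b in seq_len(nrow(bouts)))
    bout_idx[cgm_times >= bouts$start[b] & cgm_times <= bouts$end[b]] <- b
  entry <- config$glucose_mean
  for (i in seq_len(n_cgm)) {
    b <- bout_idx[i]
    if (b > 0L) {
      if (i == 1L || bout_idx[i - 1L] != b) entry <- x
      elapsed_min <- as.numeric(difftime(cgm_times[i], bouts$start[b],
                                         units = "mins"))
      x <- entry - config$bouts$drop_rate[b] * elapsed_min / 10
    } else {
      x <- config$glucose_mean + phi * (x - config$glucose_mean) + innov[i]
    }
    glucose[i] <- min(400, max(40, x))
    x <- glucose[i]
  }
  cgm <- data.frame(timestamp = cgm_times, glucose = round(glucose, 1))

  # activity streams, one record per minute
  n_min <- config$days * 1440L
  minute_times <- origin + (seq_len(n_min) - 1) * 60
  min_bout <- rep(0L, n_min)
  for (b in seq_len(nrow(bouts)))
    min_bout[minute_times >= bouts$start[b] & minute_times < bouts$end[b]] <- b

  set.seed(.channel_seed(config$seed, "heart_rate"))
  bpm <- round(stats::rnorm(n_min, 70, 4))
  in_bout <- min_bout > 0L
  bpm[in_bout] <- round(80 + 12 * config$bouts$met_level[min_bout[in_bout]] +
                          stats::rnorm(sum(in_bout), 0, 3))
  bpm <- pmin(220, pmax(40, bpm))

  set.seed(.channel_seed(config$seed, "steps"))
  steps <- stats::rpois(n_min, 4)
  steps[in_bout] <- config$bouts$steps_per_min[min_bout[in_bout]]

  set.seed(.channel_seed(config$seed, "mets"))
  met <- round(stats::runif(n_min, 1.0, 1.4), 2)
  met[in_bout] <- config$bouts$met_level[min_bout[in_bout]]

  hr_df <- data.frame(timestamp = minute_times, bpm = as.numeric(bpm))
  st_df <- data.frame(minute_start = minute_times,
                      steps = as.integer(steps))
  met_df <- data.frame(minute_start = minute_times, met = met)

  # configured gaps
  cgm_gaps <- .resolve_gaps(config, config$cgm_dropout)
  wear_gaps <- .resolve_gaps(config, config$tracker_nonwear)
  cgm <- inject_missingness(cgm, cgm_gaps, "timestamp")
  hr_df <- inject_missingness(hr_df, wear_gaps, "timestamp")
  st_df <- inject_missingness(st_df, wear_gaps, "minute_start")
  met_df <- inject_missingness(met_df, wear_gaps, "minute_start")

  sessions <- if (nrow(bouts) == 0) empty_sessions() else data.frame(
    session_id = sprintf("S%03d", seq_len(nrow(bouts))),
    activity_type = config$bouts$activity_type,
    start = bouts$start, end = bouts$end)

  trace <- glucose_trace(config$patient_id, cgm)
  bundle <- activity_bundle(config$patient_id, hr_df, st_df, met_df,
                            sessions)

  list(trace = trace, bundle = bundle,
       ground_truth = .ground_truth(config, trace, st_df, met_df,
                                    cgm_gaps, wear_gaps),
       config = config)
}

# Ground truth by direct construction: plain loops and tapply over the
# emitted minute vectors, independent of the metric pipeline.
.ground_truth <- function(config, trace, st_df, met_df, cgm_gaps,
                          wear_gaps) {
  origin <- .sim_origin(config)
  bouts <- .bout_intervals(config)
  bout_truth <- if (nrow(bouts) == 0)
    data.frame(session_id = character(), true_drop = numeric(),
               min_glucose = numeric())
  else do.call(rbind, lapply(seq_len(nrow(bouts)), function(b) {
    g <- trace$samples$glucose[trace$samples$timestamp >= bouts$start[b] &
                                 trace$samples$timestamp <= bouts$end[b]]
    drop <- 0
    if (length(g) >= 2)
      for (i in seq_along(g))
        for (j in seq_len(i - 1))
          drop <- max(drop, g[j] - g[i])
    data.frame(session_id = sprintf("S%03d", b),
               true_drop = drop,
               min_glucose = if (length(g)) min(g) else NA_real_)
  }))

  day_of <- function(t)
    floor(as.numeric(difftime(t, origin, units = "secs")) / 86400)
  epoch_of <- function(t) floor(as.numeric(t) / 900)
  met_by_epoch <- tapply(met_df$met, epoch_of(met_df$minute_start), mean)
  mvpa_epochs <- as.numeric(names(met_by_epoch))[met_by_epoch >= 3]
  mvpa_day <- day_of(.POSIXct(mvpa_epochs * 900, tz = "UTC"))
  steps_day <- day_of(st_df$minute_start)
  daily <- data.frame(day_offset = seq_len(config$days) - 1L)
  daily$true_steps <- vapply(daily$day_offset, function(d)
    sum(st_df$steps[steps_day == d]), numeric(1))
  daily$true_mvpa_min <- vapply(daily$day_offset, function(d)
    15 * sum(mvpa_day == d), numeric(1))

  nonwear_min <- sum(wear_gaps$duration_min)
  list(bouts = bout_truth, daily = daily,
       cgm_gaps = cgm_gaps, tracker_nonwear = wear_gaps,
       nonwear_fraction = nonwear_min / (config$days * 1440))
}

#' Write a simulated patient to disk
#'
#' Emits `<id>_cgm.csv`, `<id>_activity.json` and `<id>_truth.json` in the
#' package's I/O dialects.  Identical configs produce byte-identical files.
#'
#' @param sim a [simulate_patient()] result.
#' @param dir destination directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_simulated_patient <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  off <- sim$config$std_offset_min
  id <- sim$config$patient_id
  cgm_path <- file.path(dir, paste0(id, "_cgm.csv"))
  act_path <- file.path(dir, paste0(id, "_activity.json"))
  truth_path <- file.path(dir, paste0(id, "_truth.json"))
  write_cgm_csv(sim$trace, cgm_path, off)
  write_activity_json(sim$bundle, act_path, off)
  gt <- sim$ground_truth
  gt$cgm_gaps$start <- format_iso8601(gt$cgm_gaps$start, off)
  gt$tracker_nonwear$start <- format_iso8601(gt$tracker_nonwear$start, off)
  writeLines(jsonlite::toJSON(gt, dataframe = "rows", digits = NA,
                              pretty = TRUE), truth_path)
  invisible(c(cgm = cgm_path, activity = act_path, truth = truth_path))
}
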