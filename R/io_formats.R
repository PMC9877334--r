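# Reading, cleaning and writing the device-export dialects.
#
# CGM traces arrive as CSV (header `timestamp,glucose_mg_dl`); activity
# bundles as JSON with four streams (`heartRateSamples`, `stepMinutes`,
# `metMinutes`, `sessions`).  Raw vendor exports contain duplicate and
# incomplete rows; every reader routes its stream through clean_records()
# and attaches a cleaning report so no dropped record goes unaccounted.

# Physiological bounds used to decide whether a value is plausible at all.
.GLUCOSE_RANGE <- c(20, 600)
.BPM_RANGE     <- c(25, 250)

#' Construct a glucose trace
#'
#' A glucose trace is the package's container for CGM data: a patient id and
#' a data frame of timestamped interstitial glucose samples in mg/dL,
#' strictly increasing in time.
#'
#' @param patient_id opaque patient identifier.
#' @param samples data frame with columns `timestamp` (POSIXct) and
#'   `glucose` (mg/dL).
#' @return object of class `glucose_trace`.
#' @export
glucose_trace <- function(patient_id, samples) {
  stopifnot(is.data.frame(samples),
            all(c("timestamp", "glucose") %in% names(samples)))
  samples <- samples[, c("timestamp", "glucose")]
  rownames(samples) <- NULL
  if (anyDuplicated(samples$timestamp))
    stop("glucose_trace: duplicate timestamps")
  if (is.unsorted(samples$timestamp, strictly = TRUE) && nrow(samples) > 1)
    stop("glucose_trace: samples must be strictly increasing in time")
  structure(list(patient_id = as.character(patient_id), samples = samples),
            class = "glucose_trace")
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<glucose_trace> patient %s: %d samples", x$patient_id, n))
  if (n > 0)
    cat(sprintf(" [%s .. %s]", format(min(x$samples$timestamp)),
                format(max(x$samples$timestamp))))
  cat("\n")
  invisible(x)
}

#' Construct an activity bundle
#'
#' The per-patient container for wearable data: heart-rate samples,
#' per-minute step counts, per-minute METs, and recorded activity sessions.
#'
#' @param patient_id opaque patient identifier.
#' @param heart_rate data frame `timestamp`, `bpm`.
#' @param steps data frame `minute_start`, `steps`.
#' @param mets data frame `minute_start`, `met`.
#' @param sessions data frame `session_id`, `activity_type`, `start`, `end`.
#' @return object of class `activity_bundle`.
#' @export
activity_bundle <- function(patient_id,
                            heart_rate = empty_hr(),
                            steps = empty_steps(),
                            mets = empty_mets(),
                            sessions = empty_sessions()) {
  structure(list(patient_id = as.character(patient_id),
                 heart_rate = heart_rate, steps = steps, mets = mets,
                 sessions = sessions),
            class = "activity_bundle")
}

#' @export
print.activity_bundle <- function(x, ...) {
  cat(sprintf(
    "<activity_bundle> patient %s: %d HR samples, %d step minutes, %d MET minutes, %d sessions\n",
    x$patient_id, nrow(x$heart_rate), nrow(x$steps), nrow(x$mets),
    nrow(x$sessions)))
  invisible(x)
}

empty_hr <- function() {
  data.frame(timestamp = .POSIXct(numeric(), tz = "UTC"), bpm = numeric())
}
empty_steps <- function() {
  data.frame(minute_start = .POSIXct(numeric(), tz = "UTC"),
             steps = integer())
}
empty_mets <- function() {
  data.frame(minute_start = .POSIXct(numeric(), tz = "UTC"), met = numeric())
}
empty_sessions <- function() {
  data.frame(session_id = character(), activity_type = character(),
             start = .POSIXct(numeric(), tz = "UTC"),
             end = .POSIXct(numeric(), tz = "UTC"))
}

#' Clean a stream of timed records
#'
#' Removes incomplete records (missing timestamp, missing value, or value
#' outside the stream's physiological bounds), sorts by timestamp, and
#' removes duplicates.  A duplicate is a second record at an already-seen
#' timestamp; when the values differ the last-read record supersedes the
#' earlier one (vendor re-sends replace prior values).  Always succeeds:
#' `nrow(input) == nrow(output) + duplicates_removed + incomplete_removed`.
#'
#' @param records data frame carrying a timestamp column and one value
#'   column.
#' @param timestamp_col,value_col column names.
#' @param bounds length-2 numeric inclusive bounds for the value, or `NULL`
#'   for no bound check beyond non-missingness.
#' @return list with `records` (cleaned data frame) and `report` (class
#'   `cleaning_report`: counts `duplicates_removed`, `incomplete_removed`).
#' @export
clean_records <- function(records, timestamp_col = "timestamp",
                          value_col, bounds = NULL) {
  n_in <- nrow(records)
  ts <- records[[timestamp_col]]
  val <- records[[value_col]]
  ok <- !is.na(ts) & !is.na(val)
  if (!is.null(bounds))
    ok <- ok & val >= bounds[1] & val <= bounds[2]
  incomplete <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  # stable sort keeps read order among equal timestamps, so "last read"
  # is still identifiable after sorting
  records <- records[order(records[[timestamp_col]]), , drop = FALSE]
  dup <- duplicated(records[[timestamp_col]], fromLast = TRUE)
  duplicates <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  report <- structure(list(duplicates_removed = duplicates,
                           incomplete_removed = incomplete,
                           n_in = n_in, n_out = nrow(records)),
                      class = "cleaning_report")
  list(records = records, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> kept %d/%d (duplicates removed: %d, incomplete removed: %d)\n",
              x$n_out, x$n_in, x$duplicates_removed, x$incomplete_removed))
  invisible(x)
}

#' Read a CGM CSV export
#'
#' Expects the dialect `timestamp,glucose_mg_dl` with ISO-8601 offset
#' timestamps, one sample per row.  Rows failing validation (unparseable
#' timestamp, missing or out-of-range glucose) are dropped and counted; the
#' cleaning report is attached as attribute `"cleaning"`.
#'
#' @param path file path.
#' @param patient_id id to stamp on the trace (default: file name sans
#'   extension, with a trailing `_cgm` stripped).
#' @param std_offset_min standard-time offset in minutes.
#' @return a [glucose_trace()] with attribute `cleaning`.
#' @export
read_cgm_csv <- function(path, patient_id = NULL, std_offset_min = 0) {
  if (!file.exists(path)) stop("cannot read CGM file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  for (col in c("timestamp", "glucose_mg_dl"))
    if (!col %in% names(df))
      stop("CGM CSV missing mandatory column: ", col)
  if (is.null(patient_id))
    patient_id <- sub("_cgm$", "", tools::file_path_sans_ext(basename(path)))
  parsed <- data.frame(
    timestamp = parse_iso8601(df$timestamp, std_offset_min),
    glucose = suppressWarnings(as.numeric(df$glucose_mg_dl)))
  cl <- clean_records(parsed, "timestamp", "glucose", .GLUCOSE_RANGE)
  trace <- glucose_trace(patient_id, cl$records)
  attr(trace, "cleaning") <- cl$report
  trace
}

#' Write a glucose trace as CGM CSV
#'
#' Canonical form: ISO-8601 timestamps at the given standard offset,
#' glucose to one decimal place.  Re-reading reproduces the trace
#' bit-for-bit.
#'
#' @param trace a [glucose_trace()].
#' @param path destination path.
#' @param std_offset_min standard-time offset in minutes.
#' @export
write_cgm_csv <- function(trace, path, std_offset_min = 0) {
  lines <- c("timestamp,glucose_mg_dl",
             sprintf("%s,%.1f",
                     format_iso8601(trace$samples$timestamp, std_offset_min),
                     trace$samples$glucose))
  writeLines(lines, path)
  invisible(path)
}

# Pull one field out of a parsed JSON array-of-objects (a list of lists),
# stopping with the offending key path when it is absent everywhere.
.json_field <- function(arr, field, parent, required = TRUE) {
  vals <- lapply(arr, function(el) {
    if (is.null(el[[field]])) NA else el[[field]]
  })
  if (required && length(arr) > 0 && all(vapply(vals, function(v) all(is.na(v)), TRUE)))
    stop(sprintf("activity JSON schema violation at %s[].%s", parent, field))
  vals
}

#' Read an activity JSON export
#'
#' Parses the per-patient activity dialect: top-level keys
#' `heartRateSamples` (array of `timestampISO`, `bpm`), `stepMinutes`
#' (`minuteStartISO`, `steps`), `metMinutes` (`minuteStartISO`, `met`) and
#' `sessions` (`sessionId`, `activityType`, `startISO`, `endISO`).  All four
#' streams are cleaned (duplicates and incomplete entries removed and
#' counted); sessions whose end does not follow their start are dropped with
#' a warning.
#'
#' @param path file path.
#' @param patient_id id for the bundle (default: `patientId` key if present,
#'   else file name).
#' @param std_offset_min standard-time offset in minutes.
#' @return an [activity_bundle()] with attribute `cleaning` (a list of
#'   per-stream cleaning reports).
#' @export
read_activity_json <- function(path, patient_id = NULL, std_offset_min = 0) {
  if (!file.exists(path)) stop("cannot read activity file: ", path)
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("heartRateSamples", "stepMinutes", "metMinutes", "sessions"))
    if (is.null(payload[[key]]))
      stop("activity JSON schema violation: missing key ", key)
  if (is.null(patient_id))
    patient_id <- payload$patientId %||%
      sub("_activity$", "", tools::file_path_sans_ext(basename(path)))

  num_or_na <- function(v) {
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 1) NA_real_ else v
  }
  chr_or_na <- function(v) {
    if (is.null(v) || length(v) != 1) NA_character_ else as.character(v)
  }

  hr_raw <- data.frame(
    timestamp = parse_iso8601(
      vapply(.json_field(payload$heartRateSamples, "timestampISO",
                         "heartRateSamples"), chr_or_na, ""),
      std_offset_min),
    bpm = vapply(.json_field(payload$heartRateSamples, "bpm",
                             "heartRateSamples"), num_or_na, 0))
  hr <- clean_records(hr_raw, "timestamp", "bpm", .BPM_RANGE)

  st_raw <- data.frame(
    minute_start = floor_minute(parse_iso8601(
      vapply(.json_field(payload$stepMinutes, "minuteStartISO",
                         "stepMinutes"), chr_or_na, ""),
      std_offset_min)),
    steps = vapply(.json_field(payload$stepMinutes, "steps", "stepMinutes"),
                   num_or_na, 0))
  st <- clean_records(st_raw, "minute_start", "steps", c(0, Inf))
  st$records$steps <- as.integer(round(st$records$steps))

  met_raw <- data.frame(
    minute_start = floor_minute(parse_iso8601(
      vapply(.json_field(payload$metMinutes, "minuteStartISO", "metMinutes"),
             chr_or_na, ""),
      std_offset_min)),
    met = vapply(.json_field(payload$metMinutes, "met", "metMinutes"),
                 num_or_na, 0))
  met <- clean_records(met_raw, "minute_start", "met", c(0, Inf))

  ses <- data.frame(
    session_id = vapply(.json_field(payload$sessions, "sessionId",
                                    "sessions"), chr_or_na, ""),
    activity_type = vapply(.json_field(payload$sessions, "activityType",
                                       "sessions"), chr_or_na, ""),
    start = parse_iso8601(
      vapply(.json_field(payload$sessions, "startISO", "sessions"),
             chr_or_na, ""), std_offset_min),
    end = parse_iso8601(
      vapply(.json_field(payload$sessions, "endISO", "sessions"),
             chr_or_na, ""), std_offset_min))
  bad <- is.na(ses$start) | is.na(ses$end) | is.na(ses$session_id) |
    ses$end <= ses$start
  if (any(bad))
    warning(sum(bad), " invalid activity session(s) dropped (end <= start or incomplete)")
  ses <- ses[!bad, , drop = FALSE]
  ses <- ses[order(ses$start), , drop = FALSE]
  ses <- ses[!duplicated(ses$session_id), , drop = FALSE]
  rownames(ses) <- NULL

  bundle <- activity_bundle(patient_id, hr$records, st$records, met$records,
                            ses)
  attr(bundle, "cleaning") <- list(heart_rate = hr$report,
                                   steps = st$report, mets = met$report)
  bundle
}

#' Write an activity bundle as JSON
#'
#' Canonical serialization: fixed key order, ISO timestamps, bpm to one
#' decimal, MET to two decimals, integer steps.  Re-reading a written file
#' and writing it again is byte-identical.
#'
#' @param bundle an [activity_bundle()].
#' @param path destination path.
#' @param std_offset_min standard-time offset in minutes.
#' @export
write_activity_json <- function(bundle, path, std_offset_min = 0) {
  iso <- function(t) format_iso8601(t, std_offset_min)
  obj <- list(
    patientId = jsonlite::unbox(bundle$patient_id),
    heartRateSamples = mapply(function(t, b)
      list(timestampISO = jsonlite::unbox(t),
           bpm = jsonlite::unbox(as.numeric(sprintf("%.1f", b)))),
      iso(bundle$heart_rate$timestamp), bundle$heart_rate$bpm,
      SIMPLIFY = FALSE, USE.NAMES = FALSE),
    stepMinutes = mapply(function(t, s)
      list(minuteStartISO = jsonlite::unbox(t),
           steps = jsonlite::unbox(as.integer(s))),
      iso(bundle$steps$minute_start), bundle$steps$steps,
      SIMPLIFY = FALSE, USE.NAMES = FALSE),
    metMinutes = mapply(function(t, m)
      list(minuteStartISO = jsonlite::unbox(t),
           met = jsonlite::unbox(as.numeric(sprintf("%.2f", m)))),
      iso(bundle$mets$minute_start), bundle$mets$met,
      SIMPLIFY = FALSE, USE.NAMES = FALSE),
    sessions = mapply(function(id, ty, s, e)
      list(sessionId = jsonlite::unbox(id),
           activityType = jsonlite::unbox(ty),
           startISO = jsonlite::unbox(s), endISO = jsonlite::unbox(e)),
      bundle$sessions$session_id, bundle$sessions$activity_type,
      iso(bundle$sessions$start), iso(bundle$sessions$end),
      SIMPLIFY = FALSE, USE.NAMES = FALSE))
  writeLines(jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixed column order of the clinician review table
#'
#' @format character vector of the 18 column names, in writing order.
#' @export
REVIEW_TABLE_COLUMNS <- c(
  "patient_id", "period_start", "period_end",
  "cgm_wear_pct", "mean_glucose", "tir_pct", "tir_change_pp",
  "tbr70_pct", "tbr54_pct", "tar180_pct", "tar250_pct",
  "tracker_wear_pct", "mean_daily_steps", "mean_daily_mvpa_min",
  "pct_days_guideline_met", "activity_change_pct", "n_exercise_flags",
  "rank")

#' Write the prioritized review table
#'
#' Writes patient review rows as CSV in the fixed 18-column order; numeric
#' metrics to one decimal place, counts and ranks as integers, absent
#' metrics as empty fields (never zero-filled).  [read_review_table()]
#' round-trips the file.
#'
#' @param rows data frame of review rows (see [build_review_row()]).
#' @param path destination path.
#' @export
write_review_table <- function(rows, path) {
  fmt <- function(v, digits = 1) {
    ifelse(is.na(v), "", formatC(round(v, digits), format = "f",
                                 digits = digits))
  }
  if (nrow(rows) == 0) {
    writeLines(paste(REVIEW_TABLE_COLUMNS, collapse = ","), path)
    return(invisible(path))
  }
  missing_cols <- setdiff(REVIEW_TABLE_COLUMNS, names(rows))
  if (length(missing_cols) > 0)
    stop("review rows missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    patient_id = rows$patient_id,
    period_start = rows$period_start,
    period_end = rows$period_end,
    cgm_wear_pct = fmt(rows$cgm_wear_pct),
    mean_glucose = fmt(rows$mean_glucose),
    tir_pct = fmt(rows$tir_pct),
    tir_change_pp = fmt(rows$tir_change_pp),
    tbr70_pct = fmt(rows$tbr70_pct),
    tbr54_pct = fmt(rows$tbr54_pct),
    tar180_pct = fmt(rows$tar180_pct),
    tar250_pct = fmt(rows$tar250_pct),
    tracker_wear_pct = fmt(rows$tracker_wear_pct),
    mean_daily_steps = fmt(rows$mean_daily_steps),
    mean_daily_mvpa_min = fmt(rows$mean_daily_mvpa_min),
    pct_days_guideline_met = fmt(rows$pct_days_guideline_met),
    activity_change_pct = fmt(rows$activity_change_pct),
    n_exercise_flags = ifelse(is.na(rows$n_exercise_flags), "",
                              as.character(rows$n_exercise_flags)),
    rank = ifelse(is.na(rows$rank), "", as.character(rows$rank)))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a review table written by [write_review_table()]
#'
#' @param path file path.
#' @return data frame with the fixed review-table columns; empty fields
#'   become `NA`.
#' @export
read_review_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), REVIEW_TABLE_COLUMNS))
    stop("not a review table: unexpected columns in ", path)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  for (col in setdiff(REVIEW_TABLE_COLUMNS,
                      c("patient_id", "period_start", "period_end",
                        "n_exercise_flags", "rank")))
    df[[col]] <- num(df[[col]])
  df$n_exercise_flags <- as.integer(num(df$n_exercise_flags))
  df$rank <- as.integer(num(df$rank))
  df
}
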