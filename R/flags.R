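# Clinician-review flags.
#
# Per-bout exercise-dysglycemia flags: a glucose drop of at least 50 mg/dL,
# or hypoglycemia (<70 mg/dL), during a structured exercise session.  The
# drop is the maximum decline from any earlier in-bout sample to any later
# one (running-maximum excursion) — the strictest reading of "a drop during
# exercise" and verifiable against an all-pairs oracle.  Flags use raw
# glucose samples only; display interpolation never feeds them.
#
# Period-level population flags compare the CGM and activity summaries
# against configurable thresholds (low wear, guideline not met, TIR drop,
# activity drop).  Absent inputs never flag.

.empty_exercise_flags <- function() {
  data.frame(patient_id = character(), session_id = character(),
             kind = character(),
             evidence_start = .POSIXct(numeric(), tz = "UTC"),
             evidence_value = numeric(), drop_magnitude = numeric())
}

#' Detect exercise-dysglycemia flags for one bout
#'
#' Evaluates the raw glucose samples with timestamps in
#' `[bout$start, bout$end]` (inclusive).  Emits at most one `rapid_drop`
#' flag (maximum running-max excursion at least `drop_threshold`; needs at
#' least two in-bout samples) and at most one `in_bout_hypoglycemia` flag
#' (any sample strictly below `hypo_threshold`; evaluable from one sample).
#'
#' @param trace a [glucose_trace()].
#' @param bout one activity session: a list or one-row data frame with
#'   `session_id`, `start`, `end`.
#' @param drop_threshold minimum decline in mg/dL to flag (default 50).
#' @param hypo_threshold hypoglycemia bound in mg/dL, exclusive
#'   (default 70).
#' @return data frame of flags (possibly zero rows): `patient_id`,
#'   `session_id`, `kind`, `evidence_start`, `evidence_value`,
#'   `drop_magnitude` (`NA` for hypoglycemia flags).
#' @export
detect_bout_flags <- function(trace, bout, drop_threshold = 50,
                              hypo_threshold = 70) {
  stopifnot(drop_threshold > 0)
  s <- trace$samples
  s <- s[s$timestamp >= bout$start & s$timestamp <= bout$end, , drop = FALSE]
  flags <- .empty_exercise_flags()
  if (nrow(s) == 0) return(flags)
  if (nrow(s) >= 2) {
    run_max <- cummax(s$glucose)
    excursion <- run_max - s$glucose
    peak <- max(excursion)
    if (peak >= drop_threshold) {
      at <- which.max(excursion)
      flags <- rbind(flags, data.frame(
        patient_id = trace$patient_id,
        session_id = as.character(bout$session_id),
        kind = "rapid_drop",
        evidence_start = s$timestamp[at],
        evidence_value = s$glucose[at],
        drop_magnitude = peak))
    }
  }
  if (any(s$glucose < hypo_threshold)) {
    at <- which.min(s$glucose)  # evidence: the in-bout nadir
    flags <- rbind(flags, data.frame(
      patient_id = trace$patient_id,
      session_id = as.character(bout$session_id),
      kind = "in_bout_hypoglycemia",
      evidence_start = s$timestamp[at],
      evidence_value = s$glucose[at],
      drop_magnitude = NA_real_))
  }
  rownames(flags) <- NULL
  flags
}

#' Detect exercise flags for every session in a bundle
#'
#' @param trace a [glucose_trace()].
#' @param bundle an [activity_bundle()] whose sessions define the bouts.
#' @inheritParams detect_bout_flags
#' @return data frame of flags across all sessions, time-ordered.
#' @export
detect_exercise_flags <- function(trace, bundle, drop_threshold = 50,
                                  hypo_threshold = 70) {
  ses <- bundle$sessions
  if (nrow(ses) == 0) return(.empty_exercise_flags())
  out <- do.call(rbind, lapply(seq_len(nrow(ses)), function(i)
    detect_bout_flags(trace, ses[i, ], drop_threshold, hypo_threshold)))
  rownames(out) <- NULL
  out
}

#' Raise population-level flags for one patient period
#'
#' Compares a period's CGM and activity summaries against thresholds:
#' `low_cgm_wear` (wear percent below `min_cgm_wear`), `low_tracker_wear`,
#' `guideline_not_met` (percent of guideline-met days below
#' `min_guideline_pct`), `tir_drop` (TIR change at or below
#' `-tir_drop_pp` percentage points) and `activity_drop` (MVPA change at or
#' below `-activity_drop_pct` percent).  An absent metric never flags.
#'
#' @param cgm a [cgm_summary()].
#' @param act an [activity_summary()].
#' @param config flag thresholds, see [default_config()] (`$flags`).
#' @return data frame `patient_id`, `kind`, `metric_value`, `threshold`.
#' @export
population_flags <- function(cgm, act,
                             config = default_config()$flags) {
  stopifnot(identical(as.numeric(cgm$period$start),
                      as.numeric(act$period$start)),
            identical(as.numeric(cgm$period$end),
                      as.numeric(act$period$end)))
  rows <- list()
  add <- function(kind, value, threshold) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = cgm$patient_id, kind = kind,
      metric_value = value, threshold = threshold)
  }
  chk <- function(value, threshold, kind, direction) {
    if (is.na(value) || is.null(value)) return()
    hit <- if (direction == "below") value < threshold else
      value <= -threshold
    if (hit) add(kind, value, threshold)
  }
  chk(cgm$wear_pct, config$min_cgm_wear, "low_cgm_wear", "below")
  chk(act$tracker_wear_pct, config$min_tracker_wear, "low_tracker_wear",
      "below")
  chk(act$pct_days_guideline_met, config$min_guideline_pct,
      "guideline_not_met", "below")
  chk(cgm$tir_change_pp, config$tir_drop_pp, "tir_drop", "drop")
  chk(act$activity_change_pct, config$activity_drop_pct, "activity_drop",
      "drop")
  if (length(rows) == 0)
    return(data.frame(patient_id = character(), kind = character(),
                      metric_value = numeric(), threshold = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write flags as JSON Lines
#'
#' One flag object per line; POSIXct fields serialized as ISO-8601.
#'
#' @param flags data frame of exercise and/or population flags.
#' @param path destination path.
#' @param std_offset_min standard-time offset in minutes.
#' @export
write_flags_jsonl <- function(flags, path, std_offset_min = 0) {
  lines <- vapply(seq_len(nrow(flags)), function(i) {
    row <- as.list(flags[i, ])
    for (nm in names(row)) {
      if (inherits(row[[nm]], "POSIXct"))
        row[[nm]] <- format_iso8601(row[[nm]], std_offset_min)
      if (length(row[[nm]]) == 1 && is.na(row[[nm]])) row[[nm]] <- NULL
    }
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
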