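# Review-table assembly and patient prioritization.
#
# The default ordering policy is safety-first and lexicographic: more time
# in clinically significant hypoglycemia (<54) first, then more time <70,
# then worsening TIR trend, then lower TIR, with patient id as the final
# deterministic tie-break.  It is a documented, configurable stand-in —
# the published ranking algorithm of the production care model is out of
# scope — and is fully driven by the `policy` argument so alternates can
# be dropped in.

#' Assemble one patient review row
#'
#' Combines a period's CGM summary, activity summary and flags into the
#' fixed review-table row.  Absent metrics stay `NA` (never zero-filled);
#' `n_exercise_flags` counts exercise flags only (population flags are
#' reported separately).  The two summaries must cover the same period.
#'
#' @param patient_id patient identifier.
#' @param cgm a [cgm_summary()].
#' @param act an [activity_summary()].
#' @param flags data frame of exercise flags for the period (may be empty).
#' @param std_offset_min standard-time offset in minutes (for the period
#'   columns).
#' @return one-row data frame with the 18 review-table columns (rank `NA`
#'   until ranked).
#' @export
build_review_row <- function(patient_id, cgm, act, flags = NULL,
                             std_offset_min = 0) {
  if (!identical(as.numeric(cgm$period$start), as.numeric(act$period$start)) ||
      !identical(as.numeric(cgm$period$end), as.numeric(act$period$end)))
    stop("build_review_row: CGM and activity summaries cover different periods")
  n_flags <- if (is.null(flags)) 0L else
    sum(flags$kind %in% c("rapid_drop", "in_bout_hypoglycemia"))
  data.frame(
    patient_id = as.character(patient_id),
    period_start = format_iso8601(cgm$period$start, std_offset_min),
    period_end = format_iso8601(cgm$period$end, std_offset_min),
    cgm_wear_pct = cgm$wear_pct,
    mean_glucose = cgm$mean_glucose,
    tir_pct = cgm$tir_pct,
    tir_change_pp = cgm$tir_change_pp,
    tbr70_pct = cgm$tbr70_pct,
    tbr54_pct = cgm$tbr54_pct,
    tar180_pct = cgm$tar180_pct,
    tar250_pct = cgm$tar250_pct,
    tracker_wear_pct = act$tracker_wear_pct,
    mean_daily_steps = act$mean_daily_steps,
    mean_daily_mvpa_min = act$mean_daily_mvpa_min,
    pct_days_guideline_met = act$pct_days_guideline_met,
    activity_change_pct = act$activity_change_pct,
    n_exercise_flags = as.integer(n_flags),
    rank = NA_integer_)
}

#' Default prioritization policy
#'
#' An ordered key list; each entry names a review-row column, a direction
#' (`desc` ranks larger values first, `asc` smaller first), and how to
#' treat `NA` (`na_value` substitutes a neutral value).
#'
#' @return list of policy keys.
#' @export
default_ranking_policy <- function() {
  list(
    list(column = "tbr54_pct", direction = "desc", na_value = 0),
    list(column = "tbr70_pct", direction = "desc", na_value = 0),
    list(column = "tir_change_pp", direction = "asc", na_value = 0),
    list(column = "tir_pct", direction = "asc", na_value = 100),
    list(column = "patient_id", direction = "asc"))
}

#' Rank patients for review
#'
#' Sorts review rows by the policy's lexicographic keys and assigns ranks
#' `1..N` (1 = review first).  The ordering is total and
#' permutation-invariant; duplicate patient ids are an error.
#'
#' @param rows data frame of review rows ([build_review_row()]).
#' @param policy ordered key list (default [default_ranking_policy()]).
#' @return the rows reordered with `rank` set to `1..N`.
#' @export
rank_patients <- function(rows, policy = default_ranking_policy()) {
  if (nrow(rows) == 0) return(rows)
  if (anyDuplicated(rows$patient_id))
    stop("rank_patients: duplicate patient_id")
  keys <- lapply(policy, function(k) {
    v <- rows[[k$column]]
    if (is.numeric(v) && !is.null(k$na_value)) v[is.na(v)] <- k$na_value
    r <- xtfrm(v)
    if (identical(k$direction, "desc")) -r else r
  })
  ord <- do.call(order, keys)
  out <- rows[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
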