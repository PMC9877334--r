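# Timestamp handling.
#
# All device exports carry ISO-8601 timestamps with a numeric UTC offset (or
# "Z").  Internally every instant is converted once to a single fixed
# "standard time" offset (no daylight-saving shifts) and represented as a
# POSIXct whose clock reading IS the standard-time reading; downstream
# day/minute/epoch arithmetic then never has to think about zones again.

#' Parse ISO-8601 timestamps with offsets into standard time
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` followed by `Z`, `+HH:MM`, `-HH:MM`,
#' `+HHMM` or `-HHMM` (a space instead of `T` is tolerated).  Each instant is
#' shifted to the configured standard-time offset, so two inputs denoting the
#' same instant in different zones parse identically.
#'
#' @param x character vector of timestamps.
#' @param std_offset_min standard-time offset from UTC in minutes
#'   (default 0).
#' @return POSIXct vector (clock readings in standard time); unparseable
#'   entries are `NA`.
#' @export
parse_iso8601 <- function(x, std_offset_min = 0) {
  x <- trimws(as.character(x))
  x <- sub(" ", "T", x, fixed = TRUE)
  m <- regmatches(x, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})T(\\d{2}:\\d{2}:\\d{2})(?:\\.\\d+)?(Z|[+-]\\d{2}:?\\d{2})$",
    x))
  out <- rep(.POSIXct(NA_real_, tz = "UTC"), length(x))
  ok <- lengths(m) == 4L
  if (!any(ok)) return(out)
  dt <- vapply(m[ok], function(p) paste(p[2], p[3]), "")
  off <- vapply(m[ok], function(p) p[4], "")
  base <- as.POSIXct(dt, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  off_min <- ifelse(off == "Z", 0, {
    sg <- ifelse(substr(off, 1, 1) == "-", -1, 1)
    digits <- gsub("[^0-9]", "", off)
    sg * (as.numeric(substr(digits, 1, 2)) * 60 +
            as.numeric(substr(digits, 3, 4)))
  })
  out[ok] <- base - off_min * 60 + std_offset_min * 60
  out
}

#' Format standard-time instants as ISO-8601 with offset
#'
#' Inverse of [parse_iso8601()] at second precision.
#'
#' @param t POSIXct vector in standard time.
#' @param std_offset_min standard-time offset from UTC in minutes.
#' @return character vector like `"2024-03-01T08:05:00+00:00"`.
#' @export
format_iso8601 <- function(t, std_offset_min = 0) {
  sg <- if (std_offset_min < 0) "-" else "+"
  a <- abs(std_offset_min)
  suffix <- sprintf("%s%02d:%02d", sg, a %/% 60, a %% 60)
  ifelse(is.na(t), NA_character_,
         paste0(format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), suffix))
}

# Floor to the start of the containing minute / day (standard time).
floor_minute <- function(t) {
  .POSIXct(floor(as.numeric(t) / 60) * 60, tz = "UTC")
}

floor_day <- function(t) {
  .POSIXct(floor(as.numeric(t) / 86400) * 86400, tz = "UTC")
}

#' An instant at a standard-time clock reading
#'
#' Convenience constructor: `std_time("2024-03-04 16:00:00")` is the
#' POSIXct instant with that standard-time clock reading.
#'
#' @param x character datetime (`"YYYY-MM-DD"` or `"YYYY-MM-DD HH:MM:SS"`).
#' @return POSIXct.
#' @export
std_time <- function(x) {
  as.POSIXct(x, tz = "UTC")
}
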