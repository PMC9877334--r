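# Stream synchronization for display.
#
# Glucose and heart rate are drawn as line plots with linear interpolation;
# steps as a step plot with no interpolation.  A gap of more than 15 minutes
# in any one stream is never bridged: the series is broken into segments at
# such gaps and each segment is interpolated independently, so a stream that
# is absent for an hour simply shows nothing for that hour while the other
# streams continue.  Interpolation exists for visualization only — every
# metric elsewhere in the package uses raw samples.

#' Split a sample series into display segments at long gaps
#'
#' Starts a new segment exactly where the gap between consecutive samples
#' strictly exceeds `gap_threshold_min` minutes (a gap of exactly the
#' threshold stays bridged).  The segments partition the input in order.
#'
#' @param samples data frame with columns `timestamp` (POSIXct, sorted,
#'   duplicate-free) and `value`.
#' @param gap_threshold_min maximum bridgeable gap in minutes (default 15).
#' @return list of data frames, each a contiguous segment; empty list for
#'   empty input.
#' @export
segment_by_gaps <- function(samples, gap_threshold_min = 15) {
  stopifnot(gap_threshold_min > 0)
  n <- nrow(samples)
  if (n == 0) return(list())
  gaps <- diff(as.numeric(samples$timestamp))
  breaks <- which(gaps > gap_threshold_min * 60)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  mapply(function(s, e) {
    seg <- samples[s:e, , drop = FALSE]
    rownames(seg) <- NULL
    seg
  }, starts, ends, SIMPLIFY = FALSE)
}

#' Linearly interpolate one segment onto a grid
#'
#' Piecewise-linear interpolation within the segment's time span; grid
#' points outside `[first, last]` sample time get `mask = FALSE` (no
#' extrapolation).  A single-sample segment is defined only at grid points
#' falling in that sample's minute.
#'
#' @param segment data frame `timestamp`, `value` (sorted, non-empty).
#' @param grid POSIXct vector of query instants (sorted).
#' @return list with numeric `values` (NA where masked out) and logical
#'   `mask`, both the length of `grid`.
#' @export
interpolate_segment <- function(segment, grid) {
  stopifnot(nrow(segment) >= 1)
  values <- rep(NA_real_, length(grid))
  if (nrow(segment) == 1) {
    hit <- !is.na(grid) &
      floor_minute(grid) == floor_minute(segment$timestamp[1])
    values[hit] <- segment$value[1]
    return(list(values = values, mask = hit))
  }
  t0 <- as.numeric(segment$timestamp[1])
  t1 <- as.numeric(segment$timestamp[nrow(segment)])
  g <- as.numeric(grid)
  inside <- g >= t0 & g <= t1
  if (any(inside)) {
    values[inside] <- stats::approx(as.numeric(segment$timestamp),
                                    segment$value, xout = g[inside],
                                    method = "linear", ties = "ordered")$y
  }
  list(values = values, mask = inside & !is.na(values))
}

# Interpolate a whole (sorted, deduplicated) series channel-wise: segment,
# then interpolate each segment onto the grid.
.interpolate_channel <- function(samples, grid, gap_threshold_min) {
  values <- rep(NA_real_, length(grid))
  mask <- rep(FALSE, length(grid))
  at_sample <- rep(FALSE, length(grid))
  for (seg in segment_by_gaps(samples, gap_threshold_min)) {
    r <- interpolate_segment(seg, grid)
    take <- r$mask
    values[take] <- r$values[take]
    mask <- mask | take
  }
  at_sample <- as.numeric(grid) %in% as.numeric(samples$timestamp)
  list(values = values, mask = mask, interpolated = mask & !at_sample)
}

#' Build a synchronized multichannel display frame
#'
#' Places glucose, heart rate and steps on one fixed-step grid over a
#' window.  Glucose and heart rate carry per-segment interpolated line
#' values; steps carry the raw per-minute counts (no interpolation) at the
#' grid points falling in a recorded minute.  Channels are independent:
#' where one stream is absent beyond the gap threshold, only the remaining
#' channels show values.
#'
#' @param trace a [glucose_trace()] (or `NULL` for no glucose channel data).
#' @param bundle an [activity_bundle()] (or `NULL`).
#' @param window length-2 POSIXct `c(start, end)`, `start < end`.
#' @param grid_step_min grid spacing in minutes (default 1).
#' @param gap_threshold_min maximum bridgeable gap in minutes (default 15).
#' @return object of class `sync_frame`: `grid` plus per-channel `values`,
#'   `mask`, `interpolated`.
#' @export
build_overlay <- function(trace, bundle, window, grid_step_min = 1,
                          gap_threshold_min = 15) {
  start <- window[1]; end <- window[2]
  if (!(start < end)) {
    grid <- .POSIXct(numeric(), tz = "UTC")
  } else {
    npt <- floor(as.numeric(difftime(end, start, units = "mins")) /
                   grid_step_min) + 1
    grid <- start + (seq_len(npt) - 1) * grid_step_min * 60
  }
  in_window <- function(df, col) {
    df[!is.na(df[[col]]) & df[[col]] >= start & df[[col]] <= end, ,
       drop = FALSE]
  }
  none <- data.frame(timestamp = .POSIXct(numeric(), tz = "UTC"),
                     value = numeric())
  glu <- if (is.null(trace)) none else
    in_window(data.frame(timestamp = trace$samples$timestamp,
                         value = trace$samples$glucose), "timestamp")
  hr <- if (is.null(bundle)) none else
    in_window(data.frame(timestamp = bundle$heart_rate$timestamp,
                         value = bundle$heart_rate$bpm), "timestamp")

  channels <- list(
    glucose = .interpolate_channel(glu, grid, gap_threshold_min),
    heart_rate = .interpolate_channel(hr, grid, gap_threshold_min))

  # steps: raw counts, mask true only where the grid point's minute has a
  # recorded step count
  sv <- rep(NA_real_, length(grid)); sm <- rep(FALSE, length(grid))
  if (!is.null(bundle) && nrow(bundle$steps) > 0) {
    st <- in_window(data.frame(timestamp = bundle$steps$minute_start,
                               value = bundle$steps$steps), "timestamp")
    idx <- match(as.numeric(floor_minute(grid)), as.numeric(st$timestamp))
    sm <- !is.na(idx)
    sv[sm] <- st$value[idx[sm]]
  }
  channels$steps <- list(values = sv, mask = sm,
                         interpolated = rep(FALSE, length(grid)))

  structure(list(grid = grid, channels = channels,
                 grid_step_min = grid_step_min),
            class = "sync_frame")
}

#' @export
print.sync_frame <- function(x, ...) {
  cat(sprintf("<sync_frame> %d grid points at %g min", length(x$grid),
              x$grid_step_min))
  for (ch in names(x$channels))
    cat(sprintf("; %s: %d shown", ch, sum(x$channels[[ch]]$mask)))
  cat("\n")
  invisible(x)
}

#' Export a synchronized frame as tidy CSV
#'
#' One row per displayed (masked-in) grid point and channel, columns
#' `timestamp, channel, value, interpolated` — the feed for an overlay plot.
#'
#' @param frame a [build_overlay()] result.
#' @param path destination path.
#' @param std_offset_min standard-time offset in minutes.
#' @export
export_overlay <- function(frame, path, std_offset_min = 0) {
  rows <- list()
  for (ch in names(frame$channels)) {
    c_ <- frame$channels[[ch]]
    keep <- which(c_$mask)
    if (length(keep) == 0) next
    rows[[ch]] <- data.frame(
      timestamp = format_iso8601(frame$grid[keep], std_offset_min),
      channel = ch,
      value = sprintf("%.10g", c_$values[keep]),
      interpolated = ifelse(c_$interpolated[keep], "true", "false"))
  }
  out <- if (length(rows) == 0)
    data.frame(timestamp = character(), channel = character(),
               value = character(), interpolated = character())
  else do.call(rbind, rows)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Re-import an exported overlay onto a known grid
#'
#' Reconstructs per-channel values and masks from a file written by
#' [export_overlay()]; used to verify the export round-trips.
#'
#' @param path file path.
#' @param grid the POSIXct grid the frame was built on.
#' @param std_offset_min standard-time offset in minutes.
#' @return a `sync_frame`-shaped list.
#' @export
read_overlay <- function(path, grid, std_offset_min = 0) {
  df <- utils::read.csv(path, colClasses = "character")
  channels <- list()
  ts <- as.numeric(parse_iso8601(df$timestamp, std_offset_min))
  for (ch in unique(df$channel)) {
    sel <- df$channel == ch
    idx <- match(ts[sel], as.numeric(grid))
    values <- rep(NA_real_, length(grid))
    mask <- rep(FALSE, length(grid))
    interp <- rep(FALSE, length(grid))
    values[idx] <- as.numeric(df$value[sel])
    mask[idx] <- TRUE
    interp[idx] <- df$interpolated[sel] == "true"
    channels[[ch]] <- list(values = values, mask = mask,
                           interpolated = interp)
  }
  structure(list(grid = grid, channels = channels), class = "sync_frame")
}
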