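# Shared fixtures: random-object generators and the independent
# brute-force oracles the implementation is checked against.

T0 <- std_time("2024-03-04 00:00:00")

random_trace <- function(n, start = T0, interval_s = 300,
                         glucose = NULL, patient_id = "P1") {
  if (is.null(glucose)) glucose <- round(stats::runif(n, 40, 320), 1)
  glucose_trace(patient_id,
                data.frame(timestamp = start + (seq_len(n) - 1) * interval_s,
                           glucose = glucose))
}

# irregular heart-rate sampling over a period
random_hr <- function(n, start = T0, span_s = 86400) {
  ts <- sort(start + stats::runif(n, 0, span_s - 1))
  data.frame(timestamp = ts, bpm = round(stats::runif(n, 55, 170)))
}

period14 <- review_period(T0, T0 + 14 * 86400)

# a synthetic day with `mvpa_min` highly-active minutes starting 16:00
# (epoch-aligned), sedentary background elsewhere, full HR coverage
mvpa_day_bundle <- function(mvpa_min, day = T0) {
  minutes <- day + (0:1439) * 60
  met <- rep(1.2, 1440)
  hot <- seq(16 * 60, 16 * 60 + mvpa_min - 1)
  if (mvpa_min > 0) met[hot + 1] <- 6
  activity_bundle("P1",
    heart_rate = data.frame(timestamp = minutes, bpm = 70),
    steps = data.frame(minute_start = minutes,
                       steps = ifelse(seq_along(minutes) %in% (hot + 1),
                                      120L, 3L)),
    mets = data.frame(minute_start = minutes, met = met))
}

# ---- oracles ------------------------------------------------------------

# maximum decline from any earlier to any later sample: O(n^2) pairs
oracle_max_drop <- function(values) {
  if (length(values) < 2) return(NA_real_)
  drop <- 0
  for (j in seq_along(values))
    for (i in seq_len(j - 1))
      drop <- max(drop, values[i] - values[j])
  drop
}

# two-point line equation, bracketing interval found by scan
oracle_line_interp <- function(ts, vs, q) {
  if (q < ts[1] || q > ts[length(ts)]) return(NA_real_)
  for (i in seq_len(length(ts) - 1)) {
    if (q >= ts[i] && q <= ts[i + 1]) {
      if (ts[i + 1] == ts[i]) return(vs[i])
      return(vs[i] + (vs[i + 1] - vs[i]) * (q - ts[i]) / (ts[i + 1] - ts[i]))
    }
  }
  NA_real_
}

# per-sample band counting loop
oracle_band_pct <- function(glucose, lower, upper, lower_open = FALSE,
                            upper_open = FALSE) {
  hit <- 0
  for (g in glucose) {
    lo_ok <- if (lower_open) g > lower else g >= lower
    hi_ok <- if (upper_open) g < upper else g <= upper
    if (lo_ok && hi_ok) hit <- hit + 1
  }
  100 * hit / length(glucose)
}

# minute-by-minute wear scan
oracle_wear_pct <- function(ts, period_start, period_end) {
  total <- as.numeric(difftime(period_end, period_start, units = "mins"))
  worn <- 0
  m <- period_start
  while (m < period_end) {
    if (any(ts >= m & ts < m + 60)) worn <- worn + 1
    m <- m + 60
  }
  100 * worn / total
}
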