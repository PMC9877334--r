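# Gap segmentation, display interpolation and the synchronized overlay.

mk_samples <- function(minutes, values = seq_along(minutes)) {
  data.frame(timestamp = T0 + minutes * 60, value = values)
}

test_that("segments break exactly where the gap strictly exceeds the threshold", {
  segs <- segment_by_gaps(mk_samples(c(0, 5, 10, 30)), 15)
  expect_length(segs, 2)
  expect_equal(nrow(segs[[1]]), 3)
  expect_equal(nrow(segs[[2]]), 1)

  # a gap of exactly the threshold stays bridged
  expect_length(segment_by_gaps(mk_samples(c(0, 15, 30)), 15), 1)
  expect_length(segment_by_gaps(mk_samples(numeric())[0, ], 15), 0)
})

test_that("segments partition the input and shrink monotonically with the threshold", {
  set.seed(31)
  for (i in 1:25) {
    minutes <- sort(sample(0:600, sample(2:60, 1)))
    s <- mk_samples(minutes, stats::runif(length(minutes)))
    segs <- segment_by_gaps(s, 15)
    cat_df <- do.call(rbind, segs)
    rownames(cat_df) <- NULL
    expect_equal(cat_df, s)
    n_segs <- vapply(c(5, 10, 15, 30, 60), function(th)
      length(segment_by_gaps(s, th)), numeric(1))
    expect_true(all(diff(n_segs) <= 0))
  }
})

test_that("interpolation matches the two-point line oracle and never extrapolates", {
  seg <- mk_samples(c(0, 5), c(100, 110))
  grid <- T0 + seq(0, 10 * 60, by = 30)
  r <- interpolate_segment(seg, grid)
  expect_equal(r$values[grid == T0 + 150], 105)          # midpoint
  expect_equal(r$values[grid == T0 + 0], 100)            # at a sample
  expect_false(any(r$mask[grid > T0 + 300]))             # no extrapolation

  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    ts <- sort(sample(0:120, n)) * 60
    vs <- round(stats::runif(n, 50, 250), 1)
    seg <- data.frame(timestamp = T0 + ts, value = vs)
    grid <- T0 + seq(0, 120 * 60, by = 60)
    r <- interpolate_segment(seg, grid)
    for (j in seq_along(grid)) {
      expected <- oracle_line_interp(ts, vs, as.numeric(grid[j] - T0,
                                                        units = "secs"))
      if (is.na(expected)) {
        expect_false(r$mask[j])
      } else {
        expect_true(r$mask[j])
        expect_equal(r$values[j], expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("single-sample segments are shown only in their own minute", {
  seg <- mk_samples(7, 123)
  grid <- T0 + seq(0, 20 * 60, by = 60)
  r <- interpolate_segment(seg, grid)
  expect_equal(which(r$mask), 8)  # minute 7 only (grid is 0-based)
  expect_equal(r$values[8], 123)
})

test_that("overlay masks out a channel where it is absent beyond the gap rule", {
  day <- T0
  # glucose the whole window; heart rate missing 13:00-14:00
  cgm_min <- seq(12 * 60, 15 * 60, by = 5)
  trace <- glucose_trace("P1", data.frame(timestamp = day + cgm_min * 60,
                                          glucose = 120))
  hr_min <- setdiff(seq(12 * 60, 15 * 60, by = 1),
                    seq(13 * 60, 14 * 60 - 1, by = 1))
  bundle <- activity_bundle("P1",
    heart_rate = data.frame(timestamp = day + hr_min * 60, bpm = 80))
  frame <- build_overlay(trace, bundle,
                         c(day + 12 * 3600, day + 15 * 3600))
  expect_equal(length(frame$grid), 3 * 60 + 1)
  expect_true(all(frame$channels$glucose$mask))
  shown <- frame$channels$heart_rate$mask
  # nothing from the last pre-gap sample (12:59) until coverage resumes
  expect_false(any(shown[frame$grid >= day + 13 * 3600 &
                           frame$grid < day + 14 * 3600]))
  expect_true(all(shown[frame$grid < day + 13 * 3600]))
  expect_true(all(shown[frame$grid >= day + 14 * 3600]))

  # all channels empty -> all masks false
  f0 <- build_overlay(NULL, NULL, c(day, day + 3600))
  expect_false(any(vapply(f0$channels, function(ch) any(ch$mask), TRUE)))
})

test_that("steps are raw per-minute counts, never interpolated", {
  bundle <- activity_bundle("P1",
    steps = data.frame(minute_start = T0 + c(0, 60, 180), steps = c(10, 0, 30)))
  frame <- build_overlay(NULL, bundle, c(T0, T0 + 240))
  st <- frame$channels$steps
  expect_equal(st$values[st$mask], c(10, 0, 30))
  expect_false(st$mask[3])   # minute 2 has no record
  expect_false(any(st$interpolated))
})

test_that("channels are independent: dropping one leaves the others bit-identical", {
  sim <- simulate_patient(simulation_config(seed = 5, days = 1))
  win <- c(T0 + 10 * 3600, T0 + 20 * 3600)
  full <- build_overlay(sim$trace, sim$bundle, win)
  no_hr <- sim$bundle
  no_hr$heart_rate <- no_hr$heart_rate[0, ]
  part <- build_overlay(sim$trace, no_hr, win)
  expect_identical(full$channels$glucose, part$channels$glucose)
  expect_identical(full$channels$steps, part$channels$steps)
  expect_false(any(part$channels$heart_rate$mask))
})

test_that("overlay export round-trips values and masks", {
  sim <- simulate_patient(simulation_config(seed = 6, days = 1))
  win <- c(T0 + 15 * 3600, T0 + 18 * 3600)
  frame <- build_overlay(sim$trace, sim$bundle, win)
  path <- tempfile(fileext = ".csv")
  export_overlay(frame, path)
  back <- read_overlay(path, frame$grid)
  for (ch in names(frame$channels)) {
    expect_equal(back$channels[[ch]]$mask, frame$channels[[ch]]$mask)
    expect_equal(back$channels[[ch]]$values, frame$channels[[ch]]$values,
                 tolerance = 1e-9)
    expect_equal(back$channels[[ch]]$interpolated,
                 frame$channels[[ch]]$interpolated)
  }
  # one shown glucose point -> exactly one glucose data row
  one <- build_overlay(
    glucose_trace("P1", data.frame(timestamp = T0 + 300, glucose = 100)),
    NULL, c(T0, T0 + 600))
  p2 <- tempfile(fileext = ".csv")
  export_overlay(one, p2)
  expect_equal(length(readLines(p2)), 2)
})
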