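# Tracker wear, epoch aggregation, intensity classification, daily and
# period activity metrics.

test_that("wear percent counts minutes holding at least one heart-rate sample", {
  day <- review_period(T0, T0 + 86400)
  full <- data.frame(timestamp = T0 + (0:1439) * 60 + 30, bpm = 70)
  expect_equal(hr_wear_percent(full, day), 100)
  half <- data.frame(timestamp = T0 + (0:719) * 60, bpm = 70)
  expect_equal(hr_wear_percent(half, day), 50)
  # several samples in one minute count that minute once
  burst <- data.frame(timestamp = T0 + c(0, 10, 20, 59), bpm = 70)
  expect_equal(hr_wear_percent(burst, day), 100 / 1440)
})

test_that("wear percent equals the minute-scan oracle on random sampling patterns", {
  set.seed(21)
  hour <- review_period(T0, T0 + 3600)
  for (i in 1:30) {
    hr <- random_hr(sample(1:80, 1), span_s = 3600)
    expect_equal(hr_wear_percent(hr, hour),
                 oracle_wear_pct(hr$timestamp, hour$start, hour$end))
  }
})

test_that("epochs tile the day half-open and aggregate member minutes", {
  minutes <- T0 + (0:1439) * 60
  steps <- data.frame(minute_start = minutes, steps = 10L)
  mets <- data.frame(minute_start = minutes, met = 2)
  ep <- aggregate_epochs(steps, mets)
  expect_equal(nrow(ep), 96)          # 1440 / 15
  expect_equal(unique(ep$steps), 150L)
  expect_equal(unique(ep$mean_met), 2)
  expect_equal(sum(ep$steps), sum(steps$steps))

  # a minute at exactly an epoch's end instant belongs to the next epoch
  one <- data.frame(minute_start = T0 + 15 * 60, steps = 7L)
  ep2 <- aggregate_epochs(one, mets[0, ])
  expect_equal(ep2$start, T0 + 15 * 60)
  expect_error(aggregate_epochs(steps, mets, epoch_minutes = 17), "1440")
})

test_that("epoch sums match a brute-force window sum on random sparse data", {
  set.seed(22)
  for (i in 1:20) {
    mins <- sort(sample(0:2879, sample(10:200, 1)))
    steps <- data.frame(minute_start = T0 + mins * 60,
                        steps = sample(0:120, length(mins), replace = TRUE))
    mets <- data.frame(minute_start = T0 + mins * 60,
                       met = round(stats::runif(length(mins), 0.9, 9), 2))
    ep <- aggregate_epochs(steps, mets)
    for (j in seq_len(nrow(ep))) {
      in_ep <- steps$minute_start >= ep$start[j] &
        steps$minute_start < ep$start[j] + 900
      expect_equal(ep$steps[j], sum(steps$steps[in_ep]))
      expect_equal(ep$mean_met[j], mean(mets$met[in_ep]))
    }
    # every data-bearing minute belongs to exactly one epoch
    expect_equal(sum(ep$steps), sum(steps$steps))
  }
})

test_that("intensity classification is total and monotone in the cutpoints", {
  expect_equal(classify_epoch_intensity(c(1.0, 2.0, 4.5)),
               c("sedentary", "active", "highly_active"))
  expect_equal(classify_epoch_intensity(c(1.5, 3.0)),
               c("active", "highly_active"))   # lower-inclusive bins
  expect_true(is.na(classify_epoch_intensity(NA_real_)))
  # raising met_high never increases MVPA epochs
  set.seed(23)
  mets <- stats::runif(200, 0, 10)
  n_mvpa <- vapply(c(3, 4, 5, 6), function(hi)
    sum(classify_epoch_intensity(mets, c(1.5, hi)) == "highly_active"),
    numeric(1))
  expect_true(all(diff(n_mvpa) <= 0))
})

test_that("the 60-minute daily guideline switches exactly at 60 MVPA minutes", {
  d60 <- daily_activity(mvpa_day_bundle(60), as.Date("2024-03-04"))
  expect_equal(d60$mvpa_minutes, 60)
  expect_true(d60$guideline_met)
  d45 <- daily_activity(mvpa_day_bundle(45), as.Date("2024-03-04"))
  expect_equal(d45$mvpa_minutes, 45)
  expect_false(d45$guideline_met)
  # guideline_met is monotone in mvpa_minutes
  met_flags <- vapply(seq(0, 120, by = 15), function(k)
    daily_activity(mvpa_day_bundle(k), as.Date("2024-03-04"))$guideline_met,
    logical(1))
  expect_true(all(diff(met_flags) >= 0))
})

test_that("a day with no data is all-absent with guideline_met false", {
  d <- daily_activity(activity_bundle("P1"), as.Date("2024-03-04"))
  expect_true(is.na(d$total_steps))
  expect_true(is.na(d$mvpa_minutes))
  expect_true(is.na(d$tracker_wear_pct))
  expect_false(d$guideline_met)
})

test_that("daily steps equal the raw minute-sum oracle", {
  set.seed(24)
  sim <- simulate_patient(simulation_config(seed = 3, days = 2))
  for (d in 0:1) {
    day_start <- T0 + d * 86400
    da <- daily_activity(sim$bundle, day_start)
    raw <- sim$bundle$steps
    in_day <- raw$minute_start >= day_start &
      raw$minute_start < day_start + 86400
    expect_equal(da$total_steps, sum(raw$steps[in_day]))
  }
})

test_that("activity summary aggregates days and computes relative MVPA change", {
  period <- review_period(T0, T0 + 14 * 86400)
  # guideline met on exactly 7 of 14 days
  bundles <- lapply(0:13, function(d)
    mvpa_day_bundle(if (d %% 2 == 0) 60 else 0, day = T0 + d * 86400))
  merged <- activity_bundle("P1",
    heart_rate = do.call(rbind, lapply(bundles, `[[`, "heart_rate")),
    steps = do.call(rbind, lapply(bundles, `[[`, "steps")),
    mets = do.call(rbind, lapply(bundles, `[[`, "mets")))
  s <- activity_summary(merged, period)
  expect_equal(s$pct_days_guideline_met, 50)
  expect_equal(s$mean_daily_mvpa_min, 30)
  expect_true(is.na(s$activity_change_pct))

  prev <- s; prev$mean_daily_mvpa_min <- 20
  s2 <- activity_summary(merged, period, previous = prev)
  expect_equal(s2$activity_change_pct, 50)  # 20 -> 30 is +50%
})
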