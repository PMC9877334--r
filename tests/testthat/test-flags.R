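# Exercise-dysglycemia and population-level flags.

bout_at <- function(start_min = 0, duration_min = 60, id = "S1") {
  list(session_id = id, start = T0 + start_min * 60,
       end = T0 + (start_min + duration_min) * 60)
}

bout_trace <- function(glucose, interval_min = 5, start_min = 0) {
  glucose_trace("P1", data.frame(
    timestamp = T0 + (start_min + (seq_along(glucose) - 1) * interval_min) * 60,
    glucose = glucose))
}

test_that("rapid drop and in-bout hypoglycemia flag on their printed thresholds", {
  # monotone 140 -> 85: drop 55 >= 50, nadir 85 >= 70
  f1 <- detect_bout_flags(bout_trace(seq(140, 85, length.out = 12)),
                          bout_at())
  expect_equal(f1$kind, "rapid_drop")
  expect_equal(f1$drop_magnitude, 55)

  # nadir 65 with prior max 100: drop 35 < 50, hypo only
  f2 <- detect_bout_flags(bout_trace(seq(100, 65, length.out = 12)),
                          bout_at())
  expect_equal(f2$kind, "in_bout_hypoglycemia")
  expect_equal(f2$evidence_value, 65)

  # rising glucose: no flags
  f3 <- detect_bout_flags(bout_trace(seq(100, 140, length.out = 12)),
                          bout_at())
  expect_equal(nrow(f3), 0)

  # both can fire in one bout, at most once each
  f4 <- detect_bout_flags(bout_trace(seq(160, 60, length.out = 12)),
                          bout_at())
  expect_setequal(f4$kind, c("rapid_drop", "in_bout_hypoglycemia"))
  expect_equal(nrow(f4), 2)
})

test_that("a single in-bout sample cannot evaluate a drop but can flag hypoglycemia", {
  f <- detect_bout_flags(bout_trace(65), bout_at(duration_min = 4))
  expect_equal(f$kind, "in_bout_hypoglycemia")
  f2 <- detect_bout_flags(bout_trace(120), bout_at(duration_min = 4))
  expect_equal(nrow(f2), 0)
})

test_that("drop detection equals the all-pairs oracle on random bouts", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    g <- round(stats::runif(n, 45, 300), 1)
    tr <- bout_trace(g)
    f <- detect_bout_flags(tr, bout_at(duration_min = n * 5))
    oracle_drop <- oracle_max_drop(g)
    if (oracle_drop >= 50) {
      expect_equal(f$drop_magnitude[f$kind == "rapid_drop"], oracle_drop)
    } else {
      expect_false("rapid_drop" %in% f$kind)
    }
    expect_equal("in_bout_hypoglycemia" %in% f$kind, any(g < 70))
  }
})

test_that("flags are local to the bout window and threshold-monotone", {
  # a huge drop before the bout must not flag
  g <- c(300, 100, rep(100, 12))  # drop happens in first 10 minutes
  tr <- bout_trace(g)
  f <- detect_bout_flags(tr, bout_at(start_min = 15, duration_min = 50))
  expect_equal(nrow(f), 0)

  set.seed(42)
  for (i in 1:20) {
    g <- round(stats::runif(12, 50, 250), 1)
    tr <- bout_trace(g)
    b <- bout_at()
    n_flags <- vapply(c(80, 60, 50, 30, 10), function(th)
      nrow(detect_bout_flags(tr, b, drop_threshold = th)), numeric(1))
    expect_true(all(diff(n_flags) >= 0))  # lowering drop_threshold
    n_hypo <- vapply(c(54, 70, 90, 120), function(th)
      nrow(detect_bout_flags(tr, b, hypo_threshold = th)), numeric(1))
    expect_true(all(diff(n_hypo) >= 0))   # raising hypo_threshold
  }
})

test_that("flag detection is insensitive to sample insertion order", {
  set.seed(43)
  g <- round(stats::runif(20, 50, 250), 1)
  df <- data.frame(timestamp = T0 + (0:19) * 300, glucose = g)
  tr1 <- glucose_trace("P1", df)
  shuffled <- df[sample(20), ]
  cl <- clean_records(shuffled, "timestamp", "glucose", c(20, 600))
  tr2 <- glucose_trace("P1", cl$records)
  b <- bout_at(duration_min = 100)
  expect_equal(detect_bout_flags(tr1, b), detect_bout_flags(tr2, b))
})

mk_cgm_sum <- function(wear = 95, tir_change = NA_real_) {
  structure(list(patient_id = "P1",
                 period = review_period(T0, T0 + 14 * 86400),
                 wear_pct = wear, tir_change_pp = tir_change),
            class = "cgm_summary")
}
mk_act_sum <- function(wear = 90, guideline = 80, change = NA_real_) {
  structure(list(patient_id = "P1",
                 period = review_period(T0, T0 + 14 * 86400),
                 tracker_wear_pct = wear, pct_days_guideline_met = guideline,
                 activity_change_pct = change),
            class = "activity_summary")
}

test_that("population flags fire below their thresholds; absent metrics never flag", {
  f <- population_flags(mk_cgm_sum(), mk_act_sum(wear = 40))
  expect_equal(f$kind, "low_tracker_wear")
  expect_equal(f$metric_value, 40)

  expect_equal(nrow(population_flags(mk_cgm_sum(), mk_act_sum())), 0)
  f2 <- population_flags(mk_cgm_sum(wear = 60, tir_change = -5),
                         mk_act_sum(guideline = 10, change = -25))
  expect_setequal(f2$kind, c("low_cgm_wear", "guideline_not_met",
                             "tir_drop", "activity_drop"))
})

test_that("tightening any population threshold never removes a raised flag", {
  base <- default_config()$flags
  cgm <- mk_cgm_sum(wear = 72, tir_change = -4)
  act <- mk_act_sum(wear = 55, guideline = 45, change = -20)
  loose <- population_flags(cgm, act, base)
  tight <- base
  tight$min_cgm_wear <- 80; tight$min_tracker_wear <- 60
  tight$min_guideline_pct <- 60; tight$tir_drop_pp <- 3
  tight$activity_drop_pct <- 15
  tighter <- population_flags(cgm, act, tight)
  expect_true(all(loose$kind %in% tighter$kind))
  expect_gte(nrow(tighter), nrow(loose))
})

test_that("flags serialize to JSON Lines, one object per line", {
  f <- detect_bout_flags(bout_trace(seq(160, 60, length.out = 12)),
                         bout_at())
  path <- tempfile(fileext = ".jsonl")
  write_flags_jsonl(f, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  objs <- lapply(lines, jsonlite::fromJSON)
  expect_setequal(vapply(objs, `[[`, "", "kind"),
                  c("rapid_drop", "in_bout_hypoglycemia"))
})
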