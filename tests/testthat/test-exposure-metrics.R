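test_that("smoke-day counts follow the strict/inclusive threshold rules", {
  x <- c(0, 1.0, 2.5, 5.0, 12.0)
  expect_identical(count_smoke_days(x, 0), 4L)
  expect_identical(count_smoke_days(x, 2.5), 3L)
  expect_identical(count_smoke_days(x, 5.0), 2L)
  expect_identical(count_smoke_days(x, 10.0), 1L)
  # inclusive vs strict matters exactly at the threshold
  expect_identical(count_smoke_days(c(2.5, 2.5), 2.5, strict = TRUE), 0L)
  expect_error(count_smoke_days(numeric(0), 0), "empty")
  expect_error(count_smoke_days(x, -1), "non-negative")
})

test_that("smoke waves are maximal runs counted with the at-least-d rule", {
  x <- c(0, 3, 3, 0, 6, 6, 6, 6, 0)
  expect_identical(count_smoke_waves(x, 2.5, 2), 2L)
  expect_identical(count_smoke_waves(x, 2.5, 3), 1L)
  expect_identical(count_smoke_waves(x, 2.5, 4), 1L)
  # a single 3-day run contributes to durations 2 and 3, not 4
  expect_identical(count_smoke_waves(c(3, 3, 3), 2.5, 2), 1L)
  expect_identical(count_smoke_waves(c(3, 3, 3), 2.5, 3), 1L)
  expect_identical(count_smoke_waves(c(3, 3, 3), 2.5, 4), 0L)
  expect_identical(count_smoke_waves(rep(0, 50), 2.5, 2), 0L)
  expect_identical(count_smoke_waves(c(5, 5), 2.5, 3), 0L)  # too short
  expect_error(count_smoke_waves(x, 2.5, 5), "min_duration")
})

test_that("counting operations match brute-force oracles on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    v <- random_daily_vector()
    t <- sample(c(0, 2.5, 5, 10), 1)
    expect_identical(count_smoke_days(v, t), brute_smoke_days(v, t))
    d <- sample(2:4, 1)
    expect_identical(count_smoke_waves(v, max(t, 2.5), d),
                     brute_smoke_waves(v, max(t, 2.5), d))
  }
})

test_that("threshold and duration monotonicity hold for every pregnancy", {
  set.seed(202)
  for (i in 1:100) {
    v <- random_daily_vector(280)
    d25 <- count_smoke_days(v, 2.5); d5 <- count_smoke_days(v, 5)
    d10 <- count_smoke_days(v, 10)
    expect_true(count_smoke_days(v, 0) >= d25 && d25 >= d5 && d5 >= d10)
    for (t in c(2.5, 5, 10)) {
      w2 <- count_smoke_waves(v, t, 2); w3 <- count_smoke_waves(v, t, 3)
      w4 <- count_smoke_waves(v, t, 4)
      expect_true(w2 >= w3 && w3 >= w4)
      # a wave implies at least min_duration qualifying days
      if (w2 >= 1) expect_gte(count_smoke_days(v, t), 2)
      if (w4 >= 1) expect_gte(count_smoke_days(v, t), 4)
    }
  }
})

test_that("cumulative-by-week metrics use days 0..7w-1 and match re-summation", {
  const <- rep(3.3, 70)
  cm <- cumulative_by_week(const)
  expect_equal(cm$cum_mean, rep(3.3, 10))
  set.seed(7)
  v <- random_daily_vector(140)
  cm <- cumulative_by_week(v)
  # week 1 is exactly days 0..6 (elements 1..7)
  expect_equal(cm$cum_mean[1], mean(v[1:7]))
  expect_equal(cm$cum_days_gt0[1], sum(v[1:7] > 0))
  for (w in cm$week) {
    seg <- v[seq_len(7 * w)]
    expect_equal(cm$cum_mean[cm$week == w], mean(seg))
    expect_equal(cm$cum_days_ge5[cm$week == w], sum(seg >= 5))
  }
  expect_true(all(diff(cm$cum_days_gt0) >= 0))
  expect_error(cumulative_by_week(v, weeks = 21), "needs")
})

test_that("week-specific counts partition the covered days", {
  set.seed(8)
  v <- random_daily_vector(7 * 20)
  per_week <- vapply(0:19, function(w) week_specific_days(v, 0, w),
                     numeric(1))
  expect_equal(sum(per_week), count_smoke_days(v, 0))
  for (w in c(0, 7, 19))
    expect_equal(week_specific_days(v, 2.5, w),
                 brute_smoke_days(v[(7 * w + 1):(7 * w + 7)], 2.5))
  expect_equal(week_specific_days(rep(0, 70), 0, 3), 0L)
  expect_error(week_specific_days(v, 0, 20), "not fully covered")
  expect_error(week_specific_days(v, 0, 40), "0..36")
})

test_that("trimester metrics slice weeks 0-12 / 13-26 / 27+ and sum to totals", {
  set.seed(9)
  v <- random_daily_vector(280)
  tm <- trimester_metrics(v)
  expect_equal(sum(tm$days_gt0), count_smoke_days(v, 0))
  expect_equal(tm$n_days, c(91L, 98L, 91L))
  expect_equal(tm$mean_daily[2], mean(v[92:189]))
  # delivery at 26 weeks: third trimester empty, flagged via n_days = 0
  tm2 <- trimester_metrics(v[1:182])
  expect_equal(tm2$n_days[3], 0L)
  expect_true(is.na(tm2$mean_daily[3]))
})

test_that("threshold percentiles use linear interpolation", {
  expect_equal(unname(threshold_percentiles(rep(4.2, 50))), rep(4.2, 3))
  p <- threshold_percentiles(1:100)
  expect_equal(unname(p), c(50.5, 75.25, 90.1))
  set.seed(10)
  x <- rlnorm(500, 1, 1)
  expect_equal(unname(threshold_percentiles(x)),
               unname(quantile(sort(x), c(.5, .75, .9), type = 7)))
  expect_error(threshold_percentiles(numeric(0)), "empty")
})

test_that("correlation diagnostics are symmetric with unit diagonal", {
  set.seed(11)
  m <- cbind(a = rnorm(500), b = rnorm(500))
  m <- cbind(m, c = m[, "a"] * 2 + rnorm(500, 0, .1))
  cd <- correlation_diagnostics(m)
  expect_equal(diag(cd$cor), c(a = 1, b = 1, c = 1))
  expect_lt(max(abs(cd$cor - t(cd$cor))), 1e-12)
  expect_lt(abs(cd$cor["a", "b"]), 0.1)   # independent columns
  expect_gt(cd$cor["a", "c"], 0.99)
  dm <- cbind(m, z = rep(1, 500))
  cd2 <- correlation_diagnostics(dm)
  expect_identical(cd2$degenerate, "z")
  expect_true(all(is.na(cd2$cor["z", ])))
  expect_error(correlation_diagnostics(m[1:2, ]), "at least 3")
})

test_that("cohort metric table carries all thresholds and durations", {
  set.seed(12)
  daily <- replicate(5, random_daily_vector(280), simplify = FALSE)
  names(daily) <- paste0("P", 1:5)
  tab <- cohort_exposure_metrics(daily)
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("mean_daily", "days_gt0", "days_ge10",
                    "waves_ge2_5_d2", "waves_ge10_d4") %in% names(tab)))
  expect_equal(tab$days_ge5[2], count_smoke_days(daily[[2]], 5))
  expect_equal(tab$waves_ge5_d3[3], count_smoke_waves(daily[[3]], 5, 3))
})
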