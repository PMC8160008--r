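test_that("energetic averaging follows the equal-energy definition", {
  expect_equal(energetic_average(c(60, 60, 60)), 60)
  expect_equal(energetic_average(c(60, 70)), 10 * log10((1e6 + 1e7) / 2))
  expect_equal(energetic_average(42.5), 42.5)
  expect_error(energetic_average(numeric(0)), "no observations")
  set.seed(4)
  for (i in 1:25) {
    x <- runif(sample(2:200, 1), 30, 90)
    le <- energetic_average(x)
    expect_gte(le, mean(x))
    expect_gte(le, min(x))
    expect_lte(le, max(x))
    expect_equal(le, oracle_leq(x))
  }
})

test_that("window levels respect the day/night partition and coverage rule", {
  # constant level all day
  s <- make_series(rep(55, 1440))
  expect_equal(period_level(s, "2019-06-01", "full")$laeq, 55)
  expect_equal(period_level(s, "2019-06-01", "day")$laeq, 55)
  expect_equal(period_level(s, "2019-06-01", "night")$laeq, 55)

  # day at 60, night at 50: windows partition the clock
  hours <- rep(0:23, each = 60)
  lv <- ifelse(hours %in% 6:21, 60, 50)
  s <- make_series(lv)
  expect_equal(period_level(s, "2019-06-01", "day")$laeq, 60)
  expect_equal(period_level(s, "2019-06-01", "night")$laeq, 50)

  # one loud hour dominates the daily energy budget
  lv <- rep(50, 1440); lv[hours == 6] <- 70
  s <- make_series(lv)
  expect_equal(period_level(s, "2019-06-01", "full")$laeq,
               oracle_leq(lv), tolerance = 1e-12)
  expect_equal(period_level(s, "2019-06-01", "full")$laeq,
               57.0969, tolerance = 1e-4)

  # below-minimum coverage -> missing metric, coverage still reported
  s <- make_series(rep(55, 600))
  out <- period_level(s, "2019-06-01", "full")
  expect_true(is.na(out$laeq))
  expect_equal(out$coverage, 600 / 1440)
})

test_that("hourly aggregation marks under-covered hours missing", {
  s <- make_series(rep(62, 1440))
  h <- aggregate_hourly(s, "2019-06-01")
  expect_equal(h$laeq_1hr, rep(62, 24))

  s <- make_series(rep(c(50, 70), 30))  # one hour alternating 50/70
  h <- aggregate_hourly(s, "2019-06-01")
  expect_equal(h$laeq_1hr[1], 10 * log10((30 * 1e5 + 30 * 1e7) / 60))
  expect_equal(h$laeq_1hr[1], 67.0329, tolerance = 1e-4)
  expect_true(all(is.na(h$laeq_1hr[-1])))

  s <- make_series(rep(60, 10))  # 10 observed minutes, min coverage 0.5
  h <- aggregate_hourly(s, "2019-06-01", analysis_config(min_coverage = 0.5))
  expect_true(is.na(h$laeq_1hr[1]))
  expect_equal(h$coverage[1], 10 / 60)
})

test_that("event detection uses a strict threshold above the window LAeq", {
  lv <- c(rep(50, 9), 70)
  laeq <- energetic_average(lv)
  expect_equal(laeq, 10 * log10(1.09e6))
  ev <- detect_events(lv, laeq, k = 3)
  expect_equal(sum(ev), 1L)
  expect_true(ev[10])
  expect_equal(attr(ev, "threshold"), laeq + 3)

  # constant series: no events for any K > 0
  expect_equal(sum(detect_events(rep(60, 100), k = 0.5)), 0L)

  # strict inequality: a minute exactly at the threshold is not an event
  expect_false(any(detect_events(c(57, 60), laeq = 57, k = 3)))
  expect_true(any(detect_events(c(57, 60 + 1e-9), laeq = 57, k = 3)))

  # K = 0: the energetic mean lies within the range, so at least one minute
  # is below it and unflagged
  x <- runif(100, 40, 80)
  expect_lt(sum(detect_events(x, k = 0)), length(x))
})

test_that("the worked intermittency example reproduces its oracle values", {
  lv <- c(rep(50, 9), 70)
  expect_equal(energetic_average(lv), 60.3743, tolerance = 1e-4)
  expect_equal(intermittency_ratio(lv, 3), 100 * 1e7 / 1.09e7)
  expect_equal(intermittency_ratio(lv, 3), 91.7431, tolerance = 1e-4)
})

test_that("IR is zero for steady series, missing for empty windows", {
  expect_equal(intermittency_ratio(rep(63.2, 500), 3), 0)
  expect_true(is.na(intermittency_ratio(numeric(0), 3)))
})

test_that("IR matches the brute-force oracle and its invariants", {
  set.seed(7)
  for (i in 1:200) {
    x <- runif(sample(2:1440, 1), 30, 90)
    irs <- sapply(c(3, 4, 5), function(k) intermittency_ratio(x, k))
    for (j in 1:3)
      expect_equal(irs[j], oracle_ir(x, c(3, 4, 5)[j]), tolerance = 1e-9)
    # monotone non-increasing in K, in [0, 100)
    expect_true(all(diff(irs) <= 1e-12))
    expect_true(all(irs >= 0 & irs < 100))
    # shift equivariance: +c dB shifts LAeq by c, leaves IR unchanged
    cshift <- runif(1, -20, 20)
    expect_equal(energetic_average(x + cshift),
                 energetic_average(x) + cshift, tolerance = 1e-9)
    expect_equal(intermittency_ratio(x + cshift, 3), irs[1],
                 tolerance = 1e-9)
  }
})

test_that("two-level series match the closed-form IR", {
  for (p in c(0.01, 0.05, 0.1, 0.2)) {
    for (delta in c(15, 20, 25)) {
      x <- make_two_level_series(1000, p, L = 50, delta = delta)
      p_real <- mean(x > 50)
      expect_equal(intermittency_ratio(x, 3), closed_form_ir(p_real, delta),
                   tolerance = 1e-9)
    }
  }
})

test_that("daily metrics assemble all windows and propagate missingness", {
  # 7 constant days -> 7 rows, all IRs zero
  days <- as.Date("2019-06-01") + 0:6
  ts <- as.POSIXct(rep(days, each = 1440), tz = "UTC") +
    rep(0:1439, 7) * 60
  s <- minute_levels("A", ts, rep(58, 1440 * 7))
  m <- compute_metrics(s)
  expect_equal(nrow(m), 7L)
  expect_true(all(m$laeq_24hr == 58))
  expect_true(all(as.matrix(m[grep("^ir_", names(m))]) == 0))

  # a day with one injected 10-min event matches the brute-force oracle
  lv <- rep(50, 1440); lv[700:709] <- 65
  s <- make_series(lv)
  m <- daily_metrics(s, "2019-06-01")
  expect_equal(m$ir_24hr_k3, oracle_ir(lv, 3), tolerance = 1e-9)
  expect_equal(m$ir_24hr_k4, oracle_ir(lv, 4), tolerance = 1e-9)

  # no night data: night metrics missing, day metrics present
  hours <- rep(0:23, each = 60)
  day_idx <- which(hours %in% 6:21)
  ts <- as.POSIXct("2019-06-01", tz = "UTC") + (day_idx - 1) * 60
  s <- minute_levels("A", ts, rep(60, length(day_idx)))
  m <- compute_metrics(s)
  expect_true(is.na(m$l_night))
  expect_true(is.na(m$ir_night_k3))
  expect_equal(m$cov_night, 0)
  expect_equal(m$l_day, 60)
})

test_that("the spanning night convention crosses midnight", {
  # night 22:00 D .. 05:59 D+1 at 50 dBA, everything else at 70 dBA
  days <- as.Date("2019-06-01") + 0:1
  ts <- as.POSIXct(rep(days, each = 1440), tz = "UTC") + rep(0:1439, 2) * 60
  h <- as.POSIXlt(ts, tz = "UTC")$hour
  d <- as.Date(ts, tz = "UTC")
  lv <- rep(70, length(ts))
  lv[(d == days[1] & h >= 22) | (d == days[2] & h < 6)] <- 50
  s <- minute_levels("A", ts, lv)
  cfg <- analysis_config(night_convention = "spanning")
  m <- compute_metrics(s, cfg)
  expect_equal(m$l_night[m$date == days[1]], 50)
  out <- period_level(s, days[1], "night", cfg)
  expect_equal(out$laeq, 50)
  expect_equal(out$coverage, 1)
})
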