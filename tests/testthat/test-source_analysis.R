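test_that("top-k retention sorts by score with lexicographic tie-break", {
  sc <- c(car = 0.9, dog = 0.4, rain = 0.3, music = 0.1)
  expect_equal(top_k_retain(sc)$labels, c("car", "dog", "rain"))
  # tie at rank 3 broken lexicographically
  sc <- c(car = 0.9, dog = 0.4, rain = 0.3, bird = 0.3)
  expect_equal(top_k_retain(sc)$labels, c("car", "dog", "bird"))
  expect_equal(top_k_retain(sc, k = 1)$labels, "car")
  expect_error(top_k_retain(c(car = 0.9, dog = 0.4)), "at least 3")
})

make_clips <- function(l1, l2, l3) {
  clip_predictions(data.frame(
    site_id = "A",
    timestamp = sprintf("2019-06-01 08:%02d", 10 * (seq_along(l1) - 1)),
    label_1 = l1, label_2 = l2, label_3 = l3,
    score_1 = 0.9, score_2 = 0.5, score_3 = 0.2,
    stringsAsFactors = FALSE))
}

test_that("presence flags derive from the mapped top-3 labels only", {
  cl <- make_clips("car-horn", "truck", "speech")
  pr <- to_presence(cl)
  expect_equal(pr$road_transport, 1L)
  expect_equal(pr$human_speech, 1L)
  expect_equal(pr$outdoor_music + pr$aircraft + pr$nature +
                 pr$animals_and_insects + pr$other, 0L)

  # fully unmapped labels sink to 'other'
  pr <- to_presence(make_clips("zzz-1", "zzz-2", "zzz-3"))
  expect_equal(pr$other, 1L)
  expect_equal(sum(pr[CATEGORY_COLS_TEST()]), 1L)

  pr <- to_presence(make_clips("bird", "cricket", "wind"))
  expect_equal(pr$animals_and_insects, 1L)
  expect_equal(pr$nature, 1L)

  # invariant to label order within the clip
  a <- to_presence(make_clips("bird", "wind", "car"))
  b <- to_presence(make_clips("car", "bird", "wind"))
  expect_equal(a[CATEGORY_COLS_TEST()], b[CATEGORY_COLS_TEST()])
})

test_that("prevalence is the percent of clips with the category present", {
  pres <- data.frame(site_id = "A",
                     timestamp = seq_len(144),
                     road_transport = rep(c(1L, 0L), each = 72))
  out <- prevalence(pres)
  expect_equal(out$prevalence_pct, 50)
  expect_equal(out$n_clips, 144L)
  out <- prevalence(transform(pres, road_transport = 1L))
  expect_equal(out$prevalence_pct, 100)
})

test_that("pooled prevalence is the clip-weighted mean of stratum prevalences", {
  pres <- data.frame(site_id = rep(c("A", "B"), c(100, 100)),
                     road_transport = rep(c(1L, 0L), c(100, 100)))
  pooled <- prevalence(pres)
  by_site <- prevalence(pres, by = "site_id")
  expect_equal(pooled$prevalence_pct, 50)
  expect_equal(with(by_site, sum(prevalence_pct * n_clips) / sum(n_clips)),
               pooled$prevalence_pct)
  # unequal strata: still exactly clip-weighted
  pres2 <- data.frame(site_id = rep(c("A", "B"), c(30, 90)),
                      road_transport = c(rep(1L, 30), rep(0L, 90)))
  expect_equal(prevalence(pres2)$prevalence_pct, 25)
})

test_that("diurnal prevalence is stratified by hour and land use", {
  sites <- site_records(data.frame(
    site_id = "A", lat = 5.6, lon = -0.2,
    land_use = "high-density residential", road_class = "minor",
    site_type = "rotating"))
  ts <- as.POSIXct("2019-06-01", tz = "UTC") + seq(0, 1430, 10) * 60
  h <- as.POSIXlt(ts, tz = "UTC")$hour
  pres <- data.frame(site_id = "A", timestamp = ts,
                     human_speech = as.integer(h >= 8 & h <= 19))
  out <- suppressWarnings(diurnal_prevalence(pres, sites))
  sp <- out[out$category == "human_speech", ]
  expect_equal(nrow(sp), 24L)
  expect_true(all(sp$prevalence_pct[sp$hour %in% 8:19] == 100))
  expect_true(all(sp$prevalence_pct[!sp$hour %in% 8:19] == 0))
  # single clip per hour: prevalence is 0 or 100
  expect_true(all(sp$prevalence_pct %in% c(0, 100)))
})

test_that("hourly prevalence estimates recover a Bernoulli presence rate", {
  set.seed(42)
  n_days <- 21
  ts <- as.POSIXct("2019-06-01", tz = "UTC") +
    rep((0:(n_days - 1)) * 86400, each = 144) + seq(0, 1430, 10) * 60
  pres <- data.frame(site_id = "A", timestamp = ts,
                     road_transport = rbinom(length(ts), 1, 0.6),
                     hour = as.POSIXlt(ts, tz = "UTC")$hour)
  out <- prevalence(pres, by = "hour")
  out <- out[out$category == "road_transport", ]
  se <- sqrt(0.6 * 0.4 / out$n_clips) * 100
  expect_true(all(abs(out$prevalence_pct - 60) <= 3 * se))
})

test_that("level linkage drops unmatched clips and bins half-open", {
  lv <- make_series(c(57, 58, 59, 55), date = "2019-06-01", start_min = 0)
  # clips at minutes 0 and 10; only minute 0 has a level record
  pres <- data.frame(
    site_id = "S1",
    timestamp = as.POSIXct("2019-06-01", tz = "UTC") + c(0, 600),
    road_transport = c(1L, 1L))
  sites <- site_records(data.frame(
    site_id = "S1", lat = 5.6, lon = -0.2,
    land_use = "commercial-business-industrial", road_class = "major",
    site_type = "rotating"))
  out <- prevalence_by_level(pres, lv, sites)
  expect_equal(attr(out, "n_dropped"), 1L)
  rt <- out[out$category == "road_transport", ]
  expect_equal(rt$dba_bin, "(55,60]")
  expect_equal(rt$prevalence_pct, 100)

  # a minute at exactly 55.0 dBA falls in the lower bin
  lv <- make_series(c(55), date = "2019-06-01")
  pres <- data.frame(site_id = "S1",
                     timestamp = as.POSIXct("2019-06-01", tz = "UTC"),
                     road_transport = 1L)
  out <- prevalence_by_level(pres, lv, sites)
  expect_equal(out$dba_bin[out$category == "road_transport"], "(50,55]")

  # no overlap at all is an error
  pres$timestamp <- pres$timestamp + 3600
  expect_error(prevalence_by_level(pres, lv, sites), "no clip matches")
})

test_that("flight-path stratification matches a haversine oracle", {
  path <- data.frame(lat = c(5.60, 5.65), lon = c(-0.17, -0.10))
  sites <- site_records(data.frame(
    site_id = c("on-vertex", "near", "far"),
    lat = c(5.60, 5.6316, 5.20),      # 2nd site ~0.9 km off the midpoint
    lon = c(-0.17, -0.1397, -0.60),
    land_use = "commercial-business-industrial",
    road_class = "major", site_type = "rotating"))
  out <- flight_path_strata(sites, path, buffer_m = 1000)
  expect_equal(out$flight_path, c("within", "within", "outside"))
  expect_lt(out$flightpath_dist_m[1], 1)
  for (i in 1:3) {
    d_oracle <- oracle_point_polyline_m(sites$lat[i], sites$lon[i], path)
    expect_equal(out$flightpath_dist_m[i], d_oracle,
                 tolerance = 0.01 * max(1, d_oracle))
  }
  expect_error(flight_path_strata(sites,
                                  data.frame(lat = c(5, 5), lon = c(1, 1))),
               "degenerate")
  expect_error(flight_path_strata(sites, data.frame(lat = 5, lon = 1)),
               "2 vertices")
})

test_that("PPV is 100*TP/(TP+FP), missing when never predicted", {
  counts <- data.frame(category = c("road", "music", "nature", "never"),
                       tp = c(76, 0, 42, 0), fp = c(24, 10, 0, 0))
  out <- ppv(counts)
  expect_equal(out$ppv_pct, c(76, 0, 100, NA))
  expect_error(ppv(data.frame(category = "x", tp = -1, fp = 2)),
               "non-negative")
})
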