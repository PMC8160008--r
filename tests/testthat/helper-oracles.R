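# Independent brute-force oracles. Deliberately written with explicit loops
# and no shared code with the package internals.

oracle_leq <- function(levels) {
  s <- 0
  for (x in levels) s <- s + 10^(x / 10)
  10 * log10(s / length(levels))
}

oracle_ir <- function(levels, k) {
  laeq <- oracle_leq(levels)
  thr <- laeq + k
  num <- 0
  den <- 0
  for (x in levels) {
    e <- 10^(x / 10)
    den <- den + e
    if (x > thr) num <- num + e
  }
  100 * num / den
}

# exact two-sided rank-sum p-value by full enumeration of rank assignments
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for a
  all_r <- seq_len(n1 + n2)
  sets <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(all_r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  p_lo <- mean(u_all <= w_obs)
  p_hi <- mean(u_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# quartiles by sort-and-interpolate between closest order statistics
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# great-circle distance (haversine, spherical earth)
oracle_haversine_m <- function(lat1, lon1, lat2, lon2, r = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# min distance from a point to a polyline by dense sampling of each segment
oracle_point_polyline_m <- function(lat, lon, path, n_samp = 4000) {
  best <- Inf
  for (i in seq_len(nrow(path) - 1)) {
    f <- seq(0, 1, length.out = n_samp)
    plat <- path$lat[i] + f * (path$lat[i + 1] - path$lat[i])
    plon <- path$lon[i] + f * (path$lon[i + 1] - path$lon[i])
    best <- min(best, min(oracle_haversine_m(lat, lon, plat, plon)))
  }
  best
}

# IR of a two-level series: fraction p of minutes at L + delta, rest at L
closed_form_ir <- function(p, delta) {
  g <- 10^(delta / 10)
  100 * p * g / (p * g + 1 - p)
}

make_two_level_series <- function(n, p, L = 50, delta = 20) {
  n_hi <- round(n * p)
  c(rep(L + delta, n_hi), rep(L, n - n_hi))
}

# quick minute_levels builder for a single site-day
make_series <- function(levels, date = "2019-06-01", site = "S1",
                        start_min = 0) {
  ts <- as.POSIXct(date, tz = "UTC") + (start_min + seq_along(levels) - 1) * 60
  minute_levels(site, ts, levels)
}

CATEGORY_COLS_TEST <- function() {
  c("road_transport", "animals_and_insects", "outdoor_music", "human_speech",
    "aircraft", "nature", "other")
}

bind_series <- function(a, b) {
  minute_levels(c(a$site_id, b$site_id), c(a$timestamp, b$timestamp),
                c(a$level, b$level))
}

# profile in which only one category is active, with stationary presence
# probability p (no diurnal modulation, no event coupling)
single_category_profile <- function(category = "road-transport", p = 0.6,
                                    ...) {
  pr <- flat_profile(...)
  pr$coupling <- 0
  for (nm in names(pr$categories)) {
    pp <- if (nm == category) p else 0
    pr$categories[[nm]] <- list(base_p = stats::setNames(rep(pp, 4), LAND_USES),
                                hour_logit = rep(0, 24))
  }
  pr
}

# a profile with a single flat archetype and controllable event process
flat_profile <- function(base = 50, ar_sd = 0, rate_day = 0, rate_night = 0,
                         excess_med = 15, excess_sdlog = 0, dur_mean = 1,
                         land_use = "peri-urban background", ...) {
  p <- sim_profile(...)
  p$archetypes[[land_use]] <- archetype_profile(
    night_base = base, day_contrast = 0, ar_coef = 0, ar_sd = ar_sd,
    rate_day = rate_day, rate_night = rate_night, dur_mean = dur_mean,
    excess_meanlog = log(excess_med), excess_sdlog = excess_sdlog)
  p
}
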