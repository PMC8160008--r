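## Synthetic-data generator. Minute levels are built as
##   L(t) = night_base + diurnal(hour) + AR(1) noise,
## with Poisson-arriving sound events superimposed energetically: an event of
## excess D dB on a background minute at L raises it to
## 10*log10(10^(L/10) + 10^((L+D)/10)); overlapping events add their energy.
## Levels are clipped below at the instrument noise floor (simulator only --
## the metrics engine never clips). Clip streams draw per-category presence
## Bernoulli with a logit linear in hour-of-day, land use, and (for
## road-transport) the concurrent event-minute indicator.

flat24 <- function(day_value, night_value, day_hours = 6:21) {
  v <- rep(night_value, 24)
  v[day_hours + 1] <- day_value
  v
}

#' One land-use archetype's simulation parameters
#'
#' @param night_base Baseline night level (dBA).
#' @param day_contrast Day-night contrast (dBA) added during day hours, with
#'   softened shoulder hours.
#' @param ar_coef,ar_sd AR(1) coefficient and stationary sd (dB) of the
#'   short-term level noise.
#' @param rate_day,rate_night Sound-event arrival rates (events/hour).
#' @param dur_mean Mean event duration in minutes (geometric, >= 1).
#' @param excess_meanlog,excess_sdlog Lognormal parameters of the event dB
#'   excess (default median 10 dB, sd 0.5 log-units).
#' @return A list of archetype parameters.
#' @export
archetype_profile <- function(night_base, day_contrast,
                              ar_coef = 0.6, ar_sd = 2.5,
                              rate_day = 4, rate_night = 1,
                              dur_mean = 2,
                              excess_meanlog = log(10), excess_sdlog = 0.5) {
  stopifnot(rate_day >= 0, rate_night >= 0, dur_mean >= 1,
            ar_sd >= 0, abs(ar_coef) < 1)
  diurnal <- day_contrast * c(rep(0, 6),        # 00-05
                              0.6,              # 06 ramp-up
                              rep(1, 14),       # 07-20
                              0.7,              # 21 descent
                              rep(0, 2))        # 22-23
  list(night_base = night_base, day_contrast = day_contrast,
       diurnal = diurnal, ar_coef = ar_coef, ar_sd = ar_sd,
       event_rate = flat24(rate_day, rate_night),
       dur_mean = dur_mean,
       excess_meanlog = excess_meanlog, excess_sdlog = excess_sdlog)
}

#' Default simulation profile
#'
#' Archetype baselines and event rates are calibrated qualitatively so the
#' four land-use classes reproduce the reported ordering of daily levels
#' (commercial-business-industrial > high-density > medium/low-density >
#' peri-urban) and the inverse ordering of intermittency (busy areas have a
#' steady background from which events rarely emerge; quiet areas have salient
#' events). Per-category presence probabilities by land use and hour follow
#' the same qualitative pattern (road transport dominant in busy areas and in
#' the daytime, animals/insects in quiet areas at night). These defaults are
#' synthetic study conditions, not estimates from any field dataset.
#'
#' @param coupling Logit coefficient tying road-transport presence to event
#'   minutes (default 1.5).
#' @param noise_floor Instrument noise floor in dBA (default 30).
#' @return A `sim_profile` list with `archetypes`, `categories`, `coupling`,
#'   `noise_floor`, and per-category `label_pools`.
#' @export
sim_profile <- function(coupling = 1.5, noise_floor = NOISE_FLOOR_DBA) {
  arch <- list(
    "peri-urban background" =
      archetype_profile(night_base = 47, day_contrast = 7, ar_sd = 2.2,
                        rate_day = 1.3, rate_night = 0.3,
                        excess_meanlog = log(10)),
    "medium/low-density residential" =
      archetype_profile(night_base = 52, day_contrast = 7, ar_sd = 2.2,
                        rate_day = 2, rate_night = 0.8,
                        excess_meanlog = log(7.5)),
    "high-density residential" =
      archetype_profile(night_base = 58, day_contrast = 7, ar_sd = 2.2,
                        rate_day = 3.5, rate_night = 1.3,
                        excess_meanlog = log(6)),
    "commercial-business-industrial" =
      archetype_profile(night_base = 61, day_contrast = 7, ar_sd = 2.2,
                        rate_day = 12, rate_night = 1.8,
                        excess_meanlog = log(3))
  )
  base_p <- function(pu, ml, hd, cbi)
    stats::setNames(c(pu, ml, hd, cbi), LAND_USES)
  cats <- list(
    "road-transport" = list(base_p = base_p(0.40, 0.64, 0.71, 0.85),
                            hour_logit = flat24(0.45, -0.45)),
    "animals-and-insects" = list(base_p = base_p(0.65, 0.43, 0.30, 0.16),
                                 hour_logit = flat24(-0.35, 0.5)),
    "outdoor-music" = list(base_p = base_p(0.04, 0.10, 0.15, 0.09),
                           hour_logit = flat24(0.3, -0.6, day_hours = 9:22)),
    "human-speech" = list(base_p = base_p(0.08, 0.22, 0.33, 0.28),
                          hour_logit = flat24(0.4, -0.8, day_hours = 7:20)),
    "aircraft" = list(base_p = base_p(0.02, 0.02, 0.02, 0.02),
                      hour_logit = flat24(0.2, -0.2)),
    "nature" = list(base_p = base_p(0.08, 0.04, 0.03, 0.03),
                    hour_logit = rep(0, 24)),
    "other" = list(base_p = base_p(0.35, 0.35, 0.35, 0.35),
                   hour_logit = rep(0, 24))
  )
  cm <- default_category_map()
  pools <- split(cm$label, cm$category)[SOUND_CATEGORIES]
  structure(list(archetypes = arch, categories = cats, coupling = coupling,
                 noise_floor = noise_floor, label_pools = pools,
                 filler_labels = paste0("ambient-texture-", 1:6)),
            class = "sim_profile")
}

check_profile <- function(profile) {
  for (nm in names(profile$archetypes)) {
    a <- profile$archetypes[[nm]]
    if (any(a$event_rate < 0))
      stop("archetype '", nm, "': event_rate must be >= 0")
    if (a$dur_mean < 1) stop("archetype '", nm, "': dur_mean must be >= 1")
    if (a$ar_sd < 0) stop("archetype '", nm, "': ar_sd must be >= 0")
    if (abs(a$ar_coef) >= 1) stop("archetype '", nm, "': |ar_coef| must be < 1")
  }
  for (nm in names(profile$categories)) {
    p <- profile$categories[[nm]]$base_p
    if (any(p < 0 | p > 1))
      stop("category '", nm, "': base_p must be in [0, 1]")
  }
  invisible(profile)
}

#' Simulate one site's minute-level series
#'
#' @param profile A [sim_profile()].
#' @param site_id Site identifier.
#' @param land_use One of [LAND_USES]; selects the archetype.
#' @param dates Date vector of measurement days (whole days are generated).
#' @param seed Integer seed; identical (profile, seed) give byte-identical
#'   output.
#' @param p_missing Probability a minute is dropped (independent gaps,
#'   default 0).
#' @return A [minute_levels] data.frame with an extra logical `event` column
#'   marking minutes touched by at least one simulated event.
#' @export
simulate_site_levels <- function(profile, site_id, land_use, dates,
                                 seed = 1, p_missing = 0) {
  check_profile(profile)
  if (!land_use %in% names(profile$archetypes))
    stop("no archetype for land_use '", land_use, "'")
  a <- profile$archetypes[[land_use]]
  set.seed(seed)
  dates <- sort(as.Date(dates))
  ts <- as.POSIXct(rep(dates, each = 1440), tz = "UTC") + rep(0:1439, length(dates)) * 60
  n <- length(ts)
  hour <- rep(rep(0:23, each = 60), length(dates))

  innov_sd <- a$ar_sd * sqrt(1 - a$ar_coef^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                    a$ar_coef, method = "recursive"))
  bg <- a$night_base + a$diurnal[hour + 1] + noise

  # Poisson event arrivals per hour block
  n_hours <- n %/% 60L
  block_hour <- rep(0:23, length(dates))
  counts <- stats::rpois(n_hours, a$event_rate[block_hour + 1])
  n_ev <- sum(counts)
  extra <- numeric(n)
  if (n_ev > 0) {
    block <- rep.int(seq_len(n_hours), counts)
    start <- (block - 1L) * 60L + sample.int(60L, n_ev, replace = TRUE)
    dur <- 1L + stats::rgeom(n_ev, 1 / a$dur_mean)
    excess <- stats::rlnorm(n_ev, a$excess_meanlog, a$excess_sdlog)
    idx <- rep.int(start, dur) + sequence(dur) - 1L
    # events are absolute-level sources: the drawn excess is relative to the
    # archetype's daytime baseline, so their salience grows as the diurnal
    # background drops at night
    src <- a$night_base + max(a$diurnal) + rep.int(excess, dur)
    keep <- idx <= n
    agg <- rowsum(10^(src[keep] / 10), idx[keep])
    extra[as.integer(rownames(agg))] <- agg[, 1]
  }
  level <- 10 * log10(10^(bg / 10) + extra)
  level <- pmax(level, profile$noise_floor)
  keep <- if (p_missing > 0) stats::runif(n) >= p_missing else rep(TRUE, n)
  minute_levels(site_id = rep(site_id, sum(keep)), timestamp = ts[keep],
                level = level[keep], event = (extra > 0)[keep])
}

#' Simulate a coupled clip-prediction stream
#'
#' One clip per 10-minute grid point covered by the level series; grid points
#' with no level minute are skipped and counted (`n_skipped` attribute).
#' Per-category presence is Bernoulli with
#' `logit = qlogis(base_p[land_use]) + hour_logit[hour] + coupling * event`,
#' the coupling term applying to road-transport only. Present categories
#' (ranked by a drawn salience) occupy up to three label slots, each filled
#' by a label drawn from the category's pool; remaining slots are filled with
#' distinct unmapped filler labels (which resolve to "other"). Scores are
#' sorted descending.
#'
#' @param profile A [sim_profile()].
#' @param site_id Site identifier.
#' @param land_use One of [LAND_USES].
#' @param levels The site's [minute_levels] (with the simulator's `event`
#'   column; absent -> no coupling).
#' @param seed Integer seed.
#' @return A [clip_predictions] data.frame.
#' @export
simulate_clip_stream <- function(profile, site_id, land_use, levels,
                                 seed = 1) {
  check_profile(profile)
  set.seed(seed)
  tnum <- as.numeric(levels$timestamp)
  on_grid <- tnum %% 600 == 0
  idx <- which(levels$site_id == site_id & on_grid)
  site_t <- tnum[levels$site_id == site_id]
  n_grid_expected <- if (length(site_t))
    floor(max(site_t) / 600) - ceiling(min(site_t) / 600) + 1L else 0L
  ts <- levels$timestamp[idx]
  n <- length(ts)
  if (n == 0L) stop("level series covers no 10-min grid point")
  hour <- as.POSIXlt(ts, tz = "UTC")$hour
  event <- if ("event" %in% names(levels)) levels$event[idx] else rep(FALSE, n)

  cats <- names(profile$categories)
  pres <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
  for (ci in seq_along(cats)) {
    cc <- profile$categories[[cats[ci]]]
    lg <- stats::qlogis(cc$base_p[[land_use]]) + cc$hour_logit[hour + 1]
    if (cats[ci] == "road-transport") lg <- lg + profile$coupling * event
    pres[, ci] <- stats::rbinom(n, 1, stats::plogis(lg))
  }
  # salience ranks present categories into the three label slots
  sal <- matrix(stats::runif(n * length(cats)), n)
  sal[pres == 0L] <- -Inf
  slot_cat <- matrix(NA_integer_, n, 3)
  for (j in 1:3) {
    best <- max.col(sal, ties.method = "first")
    has <- sal[cbind(seq_len(n), best)] > -Inf
    slot_cat[has, j] <- best[has]
    sal[cbind(seq_len(n), best)] <- -Inf
  }
  # labels: one draw from the category pool per filled slot, fillers elsewhere
  filler_base <- sample.int(length(profile$filler_labels), n, replace = TRUE)
  labels <- matrix(NA_character_, n, 3)
  for (j in 1:3) {
    filled <- !is.na(slot_cat[, j])
    for (ci in unique(slot_cat[filled, j])) {
      pool <- profile$label_pools[[cats[ci]]]
      rows <- which(filled & slot_cat[, j] == ci)
      labels[rows, j] <- pool[sample.int(length(pool), length(rows),
                                         replace = TRUE)]
    }
    rows <- which(!filled)
    labels[rows, j] <- profile$filler_labels[
      (filler_base[rows] + j - 1L) %% length(profile$filler_labels) + 1L]
  }
  # guard against a rare duplicate draw across slots of the same category
  dup <- labels[, 2] == labels[, 1]
  labels[dup, 2] <- paste0(labels[dup, 2], "-b")
  dup <- labels[, 3] == labels[, 1] | labels[, 3] == labels[, 2]
  labels[dup, 3] <- paste0(labels[dup, 3], "-c")

  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  hi <- pmax(u1, u2, u3); lo <- pmin(u1, u2, u3); mid <- u1 + u2 + u3 - hi - lo
  out <- clip_predictions(data.frame(
    site_id = site_id, timestamp = ts,
    label_1 = labels[, 1], label_2 = labels[, 2], label_3 = labels[, 3],
    score_1 = hi, score_2 = mid, score_3 = lo,
    stringsAsFactors = FALSE))
  attr(out, "n_skipped") <- max(0L, n_grid_expected - n)
  out
}

#' Simulate a manual-validation set with known PPV
#'
#' For each category, generates `n_clips` predicted presences whose manual
#' truth is Bernoulli(target PPV), so the realized PPV converges to the
#' target as n grows. The returned counts satisfy
#' `ppv(counts) == 100 * tp / (tp + fp)` exactly.
#'
#' @param n_clips Predicted-positive clips per category (>= 1).
#' @param target_ppv Named vector of target PPVs in percent, `(0, 100]`, one
#'   per category.
#' @param seed Integer seed.
#' @return list with `truth` (per-clip manual labels), `predictions`, and
#'   `counts` (data.frame `category`, `tp`, `fp`).
#' @export
simulate_validation_set <- function(n_clips, target_ppv, seed = 1) {
  if (n_clips < 1) stop("n_clips must be >= 1")
  if (any(target_ppv <= 0 | target_ppv > 100))
    stop("target PPVs must be in (0, 100]")
  set.seed(seed)
  truth <- do.call(rbind, lapply(names(target_ppv), function(cat) {
    confirmed <- stats::rbinom(n_clips, 1, target_ppv[[cat]] / 100)
    data.frame(category = cat, clip = seq_len(n_clips),
               predicted = 1L, confirmed = confirmed,
               stringsAsFactors = FALSE)
  }))
  counts <- do.call(rbind, lapply(split(truth, truth$category), function(d)
    data.frame(category = d$category[1], tp = sum(d$confirmed),
               fp = sum(1 - d$confirmed), stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  list(truth = truth,
       predictions = truth[, c("category", "clip", "predicted")],
       counts = counts)
}

#' Simulate a full monitoring campaign
#'
#' Emulates the combined design of week-long rotating sites and year-long
#' fixed sites: rotating sites are assigned 7-day windows staggered through
#' the campaign year, fixed sites run the whole period. Land-use allocation
#' follows the study design's proportions (rotating 25/30/52/29 and fixed
#' 3/2/4/1 across CBI / high-density / medium-low / peri-urban, rescaled for
#' other site counts).
#'
#' @param profile A [sim_profile()].
#' @param n_rotating,n_fixed Site counts (defaults 136 and 10).
#' @param start Campaign start date (default "2019-04-01").
#' @param rotating_days,fixed_days Days of measurement per site type.
#' @param seed Integer seed.
#' @param clips Also simulate clip streams (default TRUE).
#' @return list with `sites` (a `site_records`), `levels` (one
#'   [minute_levels] over all sites) and `clips` (or NULL).
#' @export
simulate_campaign <- function(profile = sim_profile(),
                              n_rotating = 136, n_fixed = 10,
                              start = "2019-04-01",
                              rotating_days = 7, fixed_days = 365,
                              seed = 1, clips = TRUE) {
  check_profile(profile)
  set.seed(seed)
  start <- as.Date(start)
  alloc <- function(n, w) {
    k <- floor(n * w / sum(w))
    rem <- n - sum(k)
    if (rem > 0) k[order(n * w / sum(w) - k, decreasing = TRUE)[seq_len(rem)]] <-
        k[order(n * w / sum(w) - k, decreasing = TRUE)[seq_len(rem)]] + 1L
    k
  }
  lu_order <- c("commercial-business-industrial", "high-density residential",
                "medium/low-density residential", "peri-urban background")
  rot_n <- alloc(n_rotating, c(25, 30, 52, 29))
  fix_n <- alloc(n_fixed, c(3, 2, 4, 1))
  sites <- data.frame(
    site_id = c(sprintf("R%03d", seq_len(n_rotating)),
                sprintf("F%02d", seq_len(n_fixed))),
    land_use = c(rep(lu_order, rot_n), rep(lu_order, fix_n)),
    site_type = rep(c("rotating", "fixed"), c(n_rotating, n_fixed)),
    stringsAsFactors = FALSE)
  sites$lat <- 5.55 + stats::runif(nrow(sites), 0, 0.25)
  sites$lon <- -0.35 + stats::runif(nrow(sites), 0, 0.45)
  sites$road_class <- sample(ROAD_CLASSES, nrow(sites), replace = TRUE,
                             prob = c(7, 34, 105) / 146)
  sites <- site_records(sites[, c("site_id", "lat", "lon", "land_use",
                                  "road_class", "site_type")])

  is_rot <- sites$site_type == "rotating"
  offsets <- integer(nrow(sites))
  offsets[is_rot] <- (seq_len(sum(is_rot)) - 1L) %% 52L * 7L
  lv <- vector("list", nrow(sites))
  cl <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    nd <- if (is_rot[i]) rotating_days else fixed_days
    dates <- start + offsets[i] + seq_len(nd) - 1L
    s_seed <- (seed * 1000L + i) %% .Machine$integer.max
    lv[[i]] <- simulate_site_levels(profile, sites$site_id[i],
                                    sites$land_use[i], dates, seed = s_seed)
    if (clips)
      cl[[i]] <- simulate_clip_stream(profile, sites$site_id[i],
                                      sites$land_use[i], lv[[i]],
                                      seed = s_seed + 500000L)
  }
  levels <- as.data.frame(data.table::rbindlist(lapply(lv, as.data.frame)))
  levels <- validate_minute_levels(levels)
  clips_out <- if (clips) {
    cc <- as.data.frame(data.table::rbindlist(lapply(cl, as.data.frame)))
    class(cc) <- c("clip_predictions", "data.frame")
    cc
  } else NULL
  list(sites = sites, levels = levels, clips = clips_out)
}
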