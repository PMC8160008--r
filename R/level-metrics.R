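## Core exposure statistics: equivalent continuous sound levels over clock
## windows and the event-threshold Intermittency Ratio.
##
## All averaging of sound levels is energetic: levels are converted to the
## linear energy scale 10^(L/10), averaged, and converted back. A minute is a
## sound "event" when its LAeq_1min strictly surpasses the window LAeq plus a
## fixed cutoff K (dBA); at equality a minute is not an event. The event
## granularity is the minute, matching 1-min integrating loggers.

#' Energetic (equivalent continuous) average of sound levels
#'
#' The steady level carrying the same total energy as the fluctuating input:
#' `10*log10(mean(10^(L/10)))`. Always lies within the range of the inputs
#' and is never below their arithmetic mean.
#'
#' @param levels Non-empty numeric vector of dBA values.
#' @return The equivalent continuous level in dBA.
#' @examples
#' energetic_average(c(60, 70))  # 67.40 dBA
#' @export
energetic_average <- function(levels) {
  if (length(levels) == 0L) stop("no observations in window")
  if (any(!is.finite(levels))) stop("levels must be finite")
  10 * log10(mean(10^(levels / 10)))
}

## Minutes of `series` falling in a window on a calendar date. For the
## spanning night convention the night of date D is 22:00 D .. 05:59 D+1.
window_index <- function(series, date, window, config) {
  date <- as.Date(date)
  d <- as.Date(series$timestamp, tz = "UTC")
  h <- as.POSIXlt(series$timestamp, tz = "UTC")$hour
  if (window == "full") return(which(d == date))
  if (window == "day") return(which(d == date & h %in% config$day_hours))
  # night
  if (config$night_convention == "calendar") {
    which(d == date & h %in% config$night_hours)
  } else {
    late <- config$night_hours[config$night_hours >= 12]
    early <- config$night_hours[config$night_hours < 12]
    which((d == date & h %in% late) | (d == date + 1 & h %in% early))
  }
}

#' Window equivalent continuous level for one site-date
#'
#' Restricts a single-site series to the minutes whose wall-clock time falls
#' in the requested window on the given calendar date, and returns the
#' energetic average together with the window coverage
#' (observed / clock-expected minutes). When coverage is below
#' `config$min_coverage` the level is reported missing (`NA`), not an error.
#'
#' @param series A single-site [minute_levels] object.
#' @param date Calendar date (anything `as.Date()` accepts).
#' @param window One of `"full"`, `"day"`, `"night"`.
#' @param config An [analysis_config()].
#' @return list with `laeq` (dBA or NA) and `coverage` (fraction).
#' @export
period_level <- function(series, date, window = c("full", "day", "night"),
                         config = analysis_config()) {
  window <- match.arg(window)
  stopifnot(length(unique(series$site_id)) <= 1L)
  idx <- window_index(series, date, window, config)
  n_exp <- expected_minutes(config, window)
  cov <- length(idx) / n_exp
  laeq <- if (length(idx) && cov >= config$min_coverage)
    energetic_average(series$level[idx]) else NA_real_
  list(laeq = laeq, coverage = cov)
}

#' Hourly equivalent continuous levels for one site-date
#'
#' @inheritParams period_level
#' @return data.frame with `hour` (0-23), `laeq_1hr` (dBA, NA when the hour's
#'   coverage falls below the configured minimum) and `coverage`.
#' @export
aggregate_hourly <- function(series, date, config = analysis_config()) {
  stopifnot(length(unique(series$site_id)) <= 1L)
  date <- as.Date(date)
  d <- as.Date(series$timestamp, tz = "UTC")
  keep <- d == date
  h <- as.POSIXlt(series$timestamp[keep], tz = "UTC")$hour
  lv <- series$level[keep]
  out <- data.frame(hour = 0:23, laeq_1hr = NA_real_, coverage = 0)
  for (hr in 0:23) {
    x <- lv[h == hr]
    out$coverage[hr + 1L] <- length(x) / 60
    if (length(x) && out$coverage[hr + 1L] >= config$min_coverage)
      out$laeq_1hr[hr + 1L] <- energetic_average(x)
  }
  out
}

#' Flag event minutes in a window
#'
#' A minute is an event iff its level strictly exceeds the window LAeq plus
#' the cutoff K. The window LAeq must be computed from these same minutes,
#' which guarantees at least one non-event minute whenever K > 0.
#'
#' @param levels Window minute levels (dBA).
#' @param laeq The window's equivalent continuous level (dBA). Defaults to
#'   `energetic_average(levels)`.
#' @param k Cutoff in dBA above the window LAeq (must be > 0 for the
#'   guarantee above).
#' @return An `event_mask`: logical vector with attributes `threshold` (dBA)
#'   and `k`.
#' @export
detect_events <- function(levels, laeq = energetic_average(levels), k = 3) {
  structure(levels > laeq + k, threshold = laeq + k, k = k,
            class = "event_mask")
}

#' Intermittency Ratio of a window
#'
#' The percentage of the window's total sound energy contributed by event
#' minutes, i.e. minutes whose level strictly exceeds the window LAeq + K:
#' `IR = 100 * sum_events 10^(L/10) / sum_all 10^(L/10)`. Returns 0 when no
#' minute qualifies, and is strictly below 100 whenever K > 0. IR is
#' non-increasing in K and invariant to adding a constant to every level.
#'
#' @param levels Window minute levels (dBA); empty input yields `NA`.
#' @param k Cutoff in dBA (default 3).
#' @param laeq Window LAeq; defaults to the energetic average of `levels`.
#' @return IR in percent.
#' @examples
#' intermittency_ratio(c(rep(50, 9), 70), k = 3)  # 91.74
#' @export
intermittency_ratio <- function(levels, k = 3, laeq = NULL) {
  if (length(levels) == 0L) return(NA_real_)
  if (is.null(laeq)) laeq <- energetic_average(levels)
  e <- 10^(levels / 10)
  100 * sum(e[levels > laeq + k]) / sum(e)
}

#' Daily metric row(s) for one site
#'
#' Assembles LAeq_24hr, L_day, L_night and the Intermittency Ratios
#' IR_24hr / IR_day / IR_night for every configured cutoff, with per-window
#' coverage; sub-metrics whose window coverage is below the configured
#' minimum are missing. A thin per-date wrapper over [compute_metrics()].
#'
#' @param series A single-site [minute_levels] object.
#' @param date Calendar date.
#' @param config An [analysis_config()].
#' @return One-row `period_metrics` data.frame.
#' @export
daily_metrics <- function(series, date, config = analysis_config()) {
  stopifnot(length(unique(series$site_id)) == 1L)
  m <- compute_metrics(series, config)
  m[m$date == as.Date(date), , drop = FALSE]
}

#' Per-site, per-date metrics for a whole measurement collection
#'
#' Vectorized assembly of the daily metric set over every (site, date) with
#' any observation: the three window LAeq values, their coverages, and the
#' Intermittency Ratio per window and cutoff (columns `ir_24hr_k3`,
#' `ir_day_k3`, ...). Windows with coverage below `config$min_coverage`
#' have their LAeq and IR reported missing; coverage is always reported.
#'
#' @param series A [minute_levels] object (any number of sites).
#' @param config An [analysis_config()].
#' @return A `period_metrics` data.frame sorted by (site_id, date).
#' @export
compute_metrics <- function(series, config = analysis_config()) {
  dt <- data.table::data.table(
    site_id = series$site_id,
    date = as.Date(series$timestamp, tz = "UTC"),
    hour = as.POSIXlt(series$timestamp, tz = "UTC")$hour,
    level = series$level)
  dt[, energy := 10^(level / 10)]

  win_stats <- function(sub, wname, n_exp) {
    g <- sub[, {
      laeq <- 10 * log10(mean(energy))
      cov <- .N / n_exp
      irs <- vapply(config$cutoffs, function(k)
        100 * sum(energy[level > laeq + k]) / sum(energy), 0)
      c(list(laeq = laeq, cov = cov), as.list(irs))
    }, by = .(site_id, date)]
    irn <- paste0("ir_", wname, "_k", format(config$cutoffs, trim = TRUE))
    data.table::setnames(
      g, c("site_id", "date",
           paste0(if (wname == "24hr") "laeq_24hr" else paste0("l_", wname)),
           paste0("cov_", wname), irn))
    low <- g[[paste0("cov_", wname)]] < config$min_coverage
    if (any(low)) {
      cols <- setdiff(names(g), c("site_id", "date", paste0("cov_", wname)))
      for (cn in cols) data.table::set(g, which(low), cn, NA_real_)
    }
    g
  }

  full <- win_stats(dt, "24hr", expected_minutes(config, "full"))
  day <- win_stats(dt[hour %in% config$day_hours], "day",
                   expected_minutes(config, "day"))
  night_sub <- if (config$night_convention == "calendar") {
    dt[hour %in% config$night_hours]
  } else {
    ns <- dt[hour %in% config$night_hours]
    ns[hour < 12, date := date - 1L]
    ns
  }
  night <- win_stats(night_sub, "night", expected_minutes(config, "night"))

  out <- Reduce(function(a, b) merge(a, b, by = c("site_id", "date"),
                                     all = TRUE), list(full, day, night))
  for (cn in grep("^cov_", names(out), value = TRUE))
    data.table::set(out, which(is.na(out[[cn]])), cn, 0)
  data.table::setorder(out, site_id, date)
  fixed <- c("site_id", "date", "laeq_24hr", "l_day", "l_night",
             "cov_24hr", "cov_day", "cov_night")
  data.table::setcolorder(out, c(fixed, sort(setdiff(names(out), fixed))))
  out <- as.data.frame(out)
  class(out) <- c("period_metrics", "data.frame")
  out
}

#' @export
print.period_metrics <- function(x, ...) {
  cat(sprintf("<period_metrics> %d site-date row(s), %d site(s)\n",
              nrow(x), length(unique(x$site_id))))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 4)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
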