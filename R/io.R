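## Readers/writers for the CSV interchange formats. All timestamps are local
## wall clock (no timezone conversion anywhere in the pipeline) and the reader
## never alters level values -- no implicit noise-floor clipping.

#' Read a minute-level sound log
#'
#' Expects a comma-separated file with a header and columns `site_id`,
#' `timestamp` (ISO-8601 `YYYY-MM-DD HH:MM`) and `level` (dBA). Malformed rows
#' (unparseable timestamp or non-numeric level) are dropped, counted, and
#' reported with their line numbers via a warning and the `malformed`
#' attribute. Duplicate (site, minute) pairs are a hard error: silently
#' merging minutes would corrupt downstream event detection.
#'
#' @param path Path to the CSV file.
#' @return A [minute_levels] data.frame covering all sites in the file, with
#'   attribute `malformed` (integer line numbers of dropped rows).
#' @seealso [series_coverage()] for per-site span coverage.
#' @export
read_level_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site_id", "timestamp", "level")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("level log missing columns: ", paste(miss, collapse = ", "))
  ts <- parse_minute(raw$timestamp)
  lv <- suppressWarnings(as.numeric(raw$level))
  bad <- which(is.na(ts) | !is.finite(lv))
  if (length(bad)) {
    warning(sprintf("dropped %d malformed row(s) at line(s) %s", length(bad),
                    paste(utils::head(bad + 1L, 10), collapse = ", ")))
    ts <- ts[-bad]; lv <- lv[-bad]; raw <- raw[-bad, , drop = FALSE]
  }
  out <- minute_levels(raw$site_id, ts, lv)
  attr(out, "malformed") <- bad + 1L   # file line numbers (header = line 1)
  out
}

#' Per-site span coverage of a minute series
#'
#' Fraction of minutes observed between each site's first and last timestamp
#' (inclusive); a series of n minutes with a 2-minute gap has coverage
#' n/(n+2).
#'
#' @param x A [minute_levels] object.
#' @return data.frame with `site_id`, `n_observed`, `n_expected`, `coverage`.
#' @export
series_coverage <- function(x) {
  sp <- split(x$timestamp, x$site_id)
  out <- data.frame(
    site_id = names(sp),
    n_observed = vapply(sp, length, 1L),
    n_expected = vapply(sp, function(ts)
      as.integer(difftime(max(ts), min(ts), units = "mins")) + 1L, 1L),
    stringsAsFactors = FALSE)
  out$coverage <- out$n_observed / out$n_expected
  rownames(out) <- NULL
  out
}

#' Read a site-metadata table
#'
#' CSV with columns `site_id`, `lat`, `lon`, `land_use`, `road_class`,
#' `site_type`; validated via [site_records()].
#' @param path Path to the CSV file.
#' @return A `site_records` data.frame.
#' @export
read_site_records <- function(path) {
  site_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read per-clip classifier predictions
#'
#' Accepts either the wide format (`label_1..3`, `score_1..3`) or the long
#' format (`label`, `rank`, `score`, three rows per clip). Rows violating the
#' contract -- fewer than 3 distinct labels, scores outside `[0,1]` or not
#' non-increasing -- are rejected, counted, and reported via the `rejected`
#' attribute (a data.frame of offending clips with reasons).
#'
#' @param path Path to the CSV file.
#' @return A [clip_predictions] data.frame of the valid clips.
#' @export
read_clip_predictions <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("label", "rank", "score") %in% names(raw))) {
    raw <- long_to_wide_clips(raw)
  }
  need <- c("site_id", "timestamp", paste0("label_", 1:3), paste0("score_", 1:3))
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("clip table missing columns: ", paste(miss, collapse = ", "))
  s <- as.matrix(raw[paste0("score_", 1:3)])
  l <- raw[paste0("label_", 1:3)]
  reason <- rep(NA_character_, nrow(raw))
  incomplete <- is.na(l[[1]]) | is.na(l[[2]]) | is.na(l[[3]]) |
    l[[1]] == "" | l[[2]] == "" | l[[3]] == ""
  reason[incomplete] <- "fewer than 3 labels"
  not_desc <- !incomplete & (is.na(s[, 1] >= s[, 2]) | s[, 1] < s[, 2] | s[, 2] < s[, 3])
  reason[not_desc] <- "scores not descending"
  out_of_range <- is.na(reason) &
    (apply(!is.finite(s) | s < 0 | s > 1, 1, any))
  reason[out_of_range] <- "score outside [0,1]"
  not_distinct <- is.na(reason) &
    (l[[1]] == l[[2]] | l[[1]] == l[[3]] | l[[2]] == l[[3]])
  reason[not_distinct] <- "labels not distinct"
  keep <- is.na(reason)
  if (any(!keep))
    warning(sprintf("rejected %d clip(s): %s", sum(!keep),
                    paste(unique(reason[!keep]), collapse = "; ")))
  out <- clip_predictions(raw[keep, need, drop = FALSE])
  attr(out, "rejected") <- data.frame(
    row = which(!keep), reason = reason[!keep], stringsAsFactors = FALSE)
  out
}

long_to_wide_clips <- function(raw) {
  dt <- data.table::as.data.table(raw)
  data.table::setorder(dt, site_id, timestamp, rank)
  w <- dt[, {
    k <- .N
    lab <- c(label, rep(NA_character_, max(0, 3 - k)))[1:3]
    sc <- c(score, rep(NA_real_, max(0, 3 - k)))[1:3]
    list(label_1 = lab[1], label_2 = lab[2], label_3 = lab[3],
         score_1 = sc[1], score_2 = sc[2], score_3 = sc[3])
  }, by = .(site_id, timestamp)]
  as.data.frame(w)
}

#' Write a per-site, per-date metrics table
#'
#' Writes one row per (site, date), sorted by (site, date), with a fixed
#' column order: `site_id`, `date`, the three window LAeq values, their
#' coverages, then the Intermittency Ratios for every cutoff. Values
#' round-trip through [read_metrics_table()] to within 1e-9.
#'
#' @param metrics A `period_metrics` data.frame from [compute_metrics()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_metrics_table <- function(metrics, path) {
  df <- as.data.frame(metrics)
  if (nrow(df) == 0L) warning("writing empty metrics table (header only)")
  fixed <- c("site_id", "date", "laeq_24hr", "l_day", "l_night",
             "cov_24hr", "cov_day", "cov_night")
  ir <- sort(setdiff(names(df), fixed))
  df <- df[order(df$site_id, df$date), c(fixed, ir), drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.12g", x)
    out[is.na(x)] <- NA
    out
  })
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return A `period_metrics` data.frame.
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  num <- setdiff(names(df), c("site_id", "date"))
  df[num] <- lapply(df[num], as.numeric)
  class(df) <- c("period_metrics", "data.frame")
  df
}

#' Write a generic results table
#' @param df data.frame to write.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
write_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
  invisible(path)
}
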