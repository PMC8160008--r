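#' Instrument noise floor (dBA)
#'
#' Minimum level the sound-level meter can register. Levels below it are
#' permitted on input but flagged; the metrics engine never clips them.
#' @export
NOISE_FLOOR_DBA <- 30

## -- minute-level series ------------------------------------------------

#' Construct a minute-level sound series
#'
#' A `minute_levels` object is a data.frame with columns `site_id`,
#' `timestamp` (POSIXct, local wall-clock minutes; the study setting has no
#' daylight-saving shifts, so timestamps are stored timezone-naive as UTC)
#' and `level` (LAeq_1min in dBA). Within each site, timestamps must be
#' strictly increasing, aligned to whole minutes, and duplicate-free. Gaps
#' (missing minutes) are simply absent rows and are never filled.
#'
#' @param site_id Character vector of site identifiers.
#' @param timestamp POSIXct (or parseable character) minute timestamps.
#' @param level Numeric LAeq_1min values in dBA; must be finite.
#' @param ... Further columns carried along (e.g. simulator bookkeeping).
#' @return A `minute_levels` data.frame, sorted by (site_id, timestamp), with
#'   attribute `n_below_floor` counting levels under [NOISE_FLOOR_DBA].
#' @export
minute_levels <- function(site_id, timestamp, level, ...) {
  if (is.character(timestamp))
    timestamp <- parse_minute(timestamp)
  df <- data.frame(site_id = as.character(site_id),
                   timestamp = timestamp, level = as.numeric(level), ...,
                   stringsAsFactors = FALSE)
  validate_minute_levels(df)
}

validate_minute_levels <- function(df) {
  stopifnot(all(c("site_id", "timestamp", "level") %in% names(df)))
  if (!inherits(df$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct")
  if (any(!is.finite(df$level)))
    stop("all levels must be finite")
  secs <- as.numeric(df$timestamp) %% 60
  if (any(secs != 0))
    stop("timestamps must be aligned to whole minutes")
  df <- df[order(df$site_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  dup <- duplicated(data.frame(df$site_id, as.numeric(df$timestamp)))
  if (any(dup)) {
    shown <- utils::head(which(dup), 3)
    stop("duplicate (site, minute) pairs: ",
         paste(df$site_id[shown],
               format(df$timestamp[shown], "%Y-%m-%d %H:%M"),
               collapse = "; "))
  }
  structure(df,
            n_below_floor = sum(df$level < NOISE_FLOOR_DBA),
            class = c("minute_levels", "data.frame"))
}

parse_minute <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M")
  # allow seconds-bearing input as long as seconds are zero
  alt <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  ts[is.na(ts)] <- alt[is.na(ts)]
  ts
}

#' @export
print.minute_levels <- function(x, ...) {
  cat(sprintf("<minute_levels> %d minutes, %d site(s), %d below %g dBA floor\n",
              nrow(x), length(unique(x$site_id)),
              attr(x, "n_below_floor") %||% sum(x$level < NOISE_FLOOR_DBA),
              NOISE_FLOOR_DBA))
  if (nrow(x)) {
    cat(sprintf("  span: %s .. %s\n",
                format(min(x$timestamp), "%Y-%m-%d %H:%M"),
                format(max(x$timestamp), "%Y-%m-%d %H:%M")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## -- site records -------------------------------------------------------

#' Validate a table of monitoring-site records
#'
#' @param df data.frame with columns `site_id`, `lat`, `lon`, `land_use`
#'   (one of [LAND_USES]), `road_class` (one of [ROAD_CLASSES]) and
#'   `site_type` (`"fixed"` or `"rotating"`).
#' @return The validated data.frame with class `site_records`.
#' @export
site_records <- function(df) {
  need <- c("site_id", "lat", "lon", "land_use", "road_class", "site_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in site table")
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("coordinates out of valid lat/lon range")
  bad <- setdiff(unique(df$land_use), LAND_USES)
  if (length(bad)) stop("unknown land_use value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$road_class), ROAD_CLASSES)
  if (length(bad)) stop("unknown road_class value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$site_type), c("fixed", "rotating"))
  if (length(bad)) stop("site_type must be 'fixed' or 'rotating'")
  df <- as.data.frame(df)
  rownames(df) <- NULL
  structure(df, class = c("site_records", "data.frame"))
}

## -- clip predictions ---------------------------------------------------

#' Validate a table of per-clip classifier predictions
#'
#' Each row is one 10-s audio clip with its three retained top-ranked class
#' labels and scores: columns `site_id`, `timestamp` (on a 10-min grid),
#' `label_1..3` (distinct), `score_1..3` (in `[0,1]`, non-increasing).
#'
#' @param df Candidate data.frame (character timestamps are parsed).
#' @return A `clip_predictions` data.frame.
#' @export
clip_predictions <- function(df) {
  need <- c("site_id", "timestamp", paste0("label_", 1:3), paste0("score_", 1:3))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clip table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  if (is.character(df$timestamp)) df$timestamp <- parse_minute(df$timestamp)
  if (any(as.numeric(df$timestamp) %% 600 != 0))
    stop("clip timestamps must lie on the 10-minute grid")
  s <- as.matrix(df[paste0("score_", 1:3)])
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("scores must be in [0, 1]")
  if (any(s[, 1] < s[, 2]) || any(s[, 2] < s[, 3]))
    stop("scores must be non-increasing across ranks")
  l <- df[paste0("label_", 1:3)]
  if (any(l[[1]] == l[[2]] | l[[1]] == l[[3]] | l[[2]] == l[[3]]))
    stop("the three retained labels must be distinct")
  rownames(df) <- NULL
  structure(df, class = c("clip_predictions", "data.frame"))
}
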