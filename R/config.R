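#' Land-use archetypes
#'
#' The four land-use classes used to stratify monitoring sites: peri-urban
#' background (least built-up), medium/low-density residential (formal
#' residential), high-density residential (informal/dense residential), and
#' commercial-business-industrial areas.
#' @export
LAND_USES <- c(
  "peri-urban background",
  "medium/low-density residential",
  "high-density residential",
  "commercial-business-industrial"
)

#' Road classes
#' @export
ROAD_CLASSES <- c("major", "secondary/tertiary", "minor")

#' Sound-source categories
#'
#' Higher-order sound-source categories (adapted from ISO acoustic-environment
#' taxonomies) into which fine-grained classifier labels are grouped. `other`
#' is the sink for everything unmapped.
#' @export
SOUND_CATEGORIES <- c(
  "road-transport", "animals-and-insects", "outdoor-music",
  "human-speech", "aircraft", "nature", "other"
)

#' Analysis configuration
#'
#' Bundles the tunable conventions shared by the metric, source and summary
#' stages: the day/night window, Intermittency Ratio cutoffs, minimum data
#' coverage per window, sound-level bin edges, and flight-path geometry.
#'
#' @param day_hours Integer hours (0-23) belonging to the daytime window.
#'   Default 6:21, i.e. 06:00-21:59; the nighttime window is the complement
#'   (22:00-05:59), so the two windows always partition the 24-h day.
#' @param cutoffs Event cutoffs K in dBA above the window LAeq used for the
#'   Intermittency Ratio. Default `c(3, 4, 5)`; must be strictly positive.
#' @param min_coverage Minimum fraction of a window's expected minutes that
#'   must be observed before a metric is emitted (default 0.8). Metrics below
#'   this are reported as missing, with coverage still reported.
#' @param night_convention `"calendar"` (default): the night of date D is
#'   00:00-05:59 plus 22:00-23:59 of D, so every metric is a pure function of
#'   one calendar date. `"spanning"`: the night of D runs 22:00 of D to 05:59
#'   of D+1.
#' @param level_bin_edges Breakpoints (dBA) for binning LAeq_1min when linking
#'   sound sources to levels. Bins are half-open `(lo, hi]` with open-ended
#'   extremes. Default `seq(30, 95, 5)`.
#' @param buffer_m Flight-path buffer distance in metres (default 1000).
#' @param flight_path Optional data.frame with `lat`, `lon` columns (>= 2
#'   vertices) giving the flight-path polyline.
#' @param seed Optional integer seed recorded for downstream stages.
#' @return An object of class `noise_config` (a named list).
#' @export
analysis_config <- function(day_hours = 6:21,
                            cutoffs = c(3, 4, 5),
                            min_coverage = 0.8,
                            night_convention = c("calendar", "spanning"),
                            level_bin_edges = seq(30, 95, 5),
                            buffer_m = 1000,
                            flight_path = NULL,
                            seed = NULL) {
  night_convention <- match.arg(night_convention)
  day_hours <- sort(unique(as.integer(day_hours)))
  if (length(day_hours) == 0L || any(day_hours < 0L | day_hours > 23L))
    stop("day_hours must be hours in 0..23")
  if (length(day_hours) == 24L)
    stop("day window must leave a non-empty night window")
  if (any(!is.finite(cutoffs)) || any(cutoffs <= 0))
    stop("cutoffs must be strictly positive dBA values")
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 1)
    stop("min_coverage must be in [0, 1]")
  if (length(level_bin_edges) < 2L || is.unsorted(level_bin_edges, strictly = TRUE))
    stop("level_bin_edges must be strictly increasing")
  if (!is.null(flight_path)) flight_path <- check_flight_path(flight_path)
  structure(list(
    day_hours = day_hours,
    night_hours = setdiff(0:23, day_hours),
    cutoffs = sort(cutoffs),
    min_coverage = min_coverage,
    night_convention = night_convention,
    level_bin_edges = level_bin_edges,
    buffer_m = buffer_m,
    flight_path = flight_path,
    seed = seed
  ), class = "noise_config")
}

check_flight_path <- function(fp) {
  fp <- as.data.frame(fp)
  if (!all(c("lat", "lon") %in% names(fp)))
    stop("flight_path needs 'lat' and 'lon' columns")
  if (nrow(fp) < 2L) stop("flight_path polyline needs at least 2 vertices")
  if (any(abs(fp$lat) > 90) || any(abs(fp$lon) > 180))
    stop("flight_path coordinates out of range")
  fp[, c("lat", "lon")]
}

#' Read an analysis configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [analysis_config()]; unknown keys
#' are an error. `flight_path` may be given as a list of `{lat, lon}` maps.
#'
#' @param path Path to a YAML file.
#' @return A `noise_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$flight_path))
    raw$flight_path <- do.call(rbind, lapply(raw$flight_path, as.data.frame))
  do.call(analysis_config, raw)
}

#' @export
print.noise_config <- function(x, ...) {
  cat("<noise_config>\n")
  cat(sprintf("  day window  : %02d:00-%02d:59\n",
              min(x$day_hours), max(x$day_hours)))
  cat(sprintf("  IR cutoffs  : +%s dBA\n", paste(x$cutoffs, collapse = ", +")))
  cat(sprintf("  min coverage: %.2f\n", x$min_coverage))
  cat(sprintf("  night conv. : %s\n", x$night_convention))
  invisible(x)
}

## Expected minutes per window, fixed by the clock.
expected_minutes <- function(config, window = c("full", "day", "night")) {
  window <- match.arg(window)
  switch(window,
         full  = 1440L,
         day   = 60L * length(config$day_hours),
         night = 60L * length(config$night_hours))
}
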