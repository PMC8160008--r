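## Post-processing of per-clip classifier output: mapping fine labels to the
## seven source categories, presence flags, prevalence (% site-time) across
## strata, level-source linkage, flight-path stratification, and PPV
## validation.

## column-safe names for the seven categories
category_column <- function(x) gsub("[^a-z]+", "_", x)
CATEGORY_COLS <- category_column(SOUND_CATEGORIES)

#' Default fine-label to category map
#'
#' Maps common urban sound-class labels (AudioSet-style ontology) to the
#' seven source categories. The map is an ordinary data.frame and is meant
#' to be edited/extended; any label not present resolves to `"other"`.
#'
#' @return data.frame with columns `label`, `category`.
#' @export
default_category_map <- function() {
  pools <- list(
    "road-transport" = c("car", "truck", "bus", "motorcycle", "car-horn",
                         "honk", "engine", "traffic", "tire-squeal", "siren",
                         "vehicle", "motorbike", "brake-squeal", "reversing-beep"),
    "animals-and-insects" = c("dog", "bird", "rooster", "chicken", "goat",
                              "sheep", "cat", "crow", "cricket", "cicada",
                              "insect", "frog", "bee", "livestock"),
    "outdoor-music" = c("music", "drum", "singing", "percussion", "guitar",
                        "bass-music", "dj", "brass-band", "choir"),
    "human-speech" = c("speech", "conversation", "shout", "child-speech",
                       "crowd", "chant", "preaching", "laughter"),
    "aircraft" = c("airplane", "aircraft-engine", "helicopter", "jet",
                   "propeller-plane"),
    "nature" = c("wind", "rain", "thunder", "thunderstorm", "water",
                 "stream", "waves", "rustling-leaves"),
    "other" = c("construction", "generator", "church-bell", "hammering",
                "air-conditioning", "white-noise", "static", "silence",
                "footsteps", "door-slam", "alarm", "sweeping")
  )
  data.frame(label = unlist(pools, use.names = FALSE),
             category = rep(names(pools), lengths(pools)),
             stringsAsFactors = FALSE)
}

#' Retain the top-k scored labels of one clip
#'
#' Sorts by descending score, breaking ties by lexicographic label order for
#' determinism, and keeps the k best distinct labels.
#'
#' @param scores Named numeric vector of per-label scores in `[0,1]`.
#' @param k Number of labels to retain (default 3).
#' @return list with `labels` (character, length k) and `scores` (descending).
#' @export
top_k_retain <- function(scores, k = 3) {
  if (is.null(names(scores)) || any(names(scores) == ""))
    stop("scores must be a named vector")
  scores <- scores[!duplicated(names(scores))]
  if (length(scores) < k)
    stop(sprintf("need at least %d scored labels, got %d", k, length(scores)))
  ord <- order(-scores, names(scores))
  list(labels = names(scores)[ord][seq_len(k)],
       scores = unname(scores[ord][seq_len(k)]))
}

#' Derive per-category presence flags from clip predictions
#'
#' A category is present in a clip iff at least one of its three retained
#' labels maps to it; categories are not mutually exclusive. Unknown labels
#' resolve to `"other"`, so every clip has at least one category present.
#'
#' @param clips A [clip_predictions] data.frame.
#' @param map A label-category map as from [default_category_map()].
#' @return A `presence_records` data.frame: `site_id`, `timestamp`, and one
#'   0/1 column per category (`road_transport`, ..., `other`).
#' @export
to_presence <- function(clips, map = default_category_map()) {
  bad <- setdiff(unique(map$category), SOUND_CATEGORIES)
  if (length(bad)) stop("map contains unknown categories: ",
                        paste(bad, collapse = ", "))
  lookup <- stats::setNames(map$category, map$label)
  out <- data.frame(site_id = clips$site_id, timestamp = clips$timestamp,
                    stringsAsFactors = FALSE)
  cats <- vapply(1:3, function(j) {
    cc <- unname(lookup[clips[[paste0("label_", j)]]])
    ifelse(is.na(cc), "other", cc)
  }, character(nrow(clips)))
  if (nrow(clips) == 1L) cats <- matrix(cats, nrow = 1L)
  for (i in seq_along(SOUND_CATEGORIES)) {
    out[[CATEGORY_COLS[i]]] <-
      as.integer(rowSums(cats == SOUND_CATEGORIES[i]) > 0)
  }
  class(out) <- c("presence_records", "data.frame")
  out
}

#' Prevalence of each source category across strata
#'
#' Prevalence is the percentage of clips in a stratum in which a category is
#' present -- a measure of site-time when sites are pooled. Pooling is
#' clip-weighted: the prevalence of a union of strata equals the
#' clip-count-weighted mean of the stratum prevalences.
#'
#' @param presence A `presence_records` data.frame, optionally carrying extra
#'   stratum columns (e.g. after merging site metadata or adding `hour`).
#' @param by Character vector of stratum column names (empty = pooled).
#' @return A `prevalence_table`: one row per stratum x category with
#'   `n_clips`, `n_present`, `prevalence_pct`.
#' @export
prevalence <- function(presence, by = character()) {
  miss <- setdiff(by, names(presence))
  if (length(miss)) stop("missing stratum column(s): ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(presence)
  if (nrow(dt) == 0L) stop("no presence records")
  cols <- intersect(CATEGORY_COLS, names(dt))
  long <- data.table::melt(dt, id.vars = c(by),
                           measure.vars = cols,
                           variable.name = "category", value.name = "present")
  g <- long[, .(n_clips = .N, n_present = sum(present),
                prevalence_pct = 100 * mean(present)),
            by = c(by, "category")]
  g[, category := as.character(category)]
  data.table::setorderv(g, c(by, "category"))
  out <- as.data.frame(g)
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Diurnal prevalence per category and land use
#'
#' Prevalence stratified by hour of day (0-23) and land use; hours with no
#' clips in a stratum are omitted (with a warning when that happens).
#'
#' @param presence A `presence_records` data.frame.
#' @param sites A `site_records` data.frame (for `land_use`).
#' @return A `prevalence_table` with `hour` and `land_use` strata.
#' @export
diurnal_prevalence <- function(presence, sites) {
  df <- merge(as.data.frame(presence),
              as.data.frame(sites)[, c("site_id", "land_use")], by = "site_id")
  df$hour <- as.POSIXlt(df$timestamp, tz = "UTC")$hour
  out <- prevalence(df, by = c("land_use", "hour"))
  n_strata <- nrow(unique(out[, c("land_use", "hour")]))
  if (n_strata < 24L * length(unique(df$land_use)))
    warning("some (land_use, hour) strata have no clips and are omitted")
  out
}

#' Prevalence by concurrent sound-level bin
#'
#' Joins each clip to the LAeq_1min of its enclosing minute (the 10-s clip is
#' taken to represent its whole minute), bins the level into half-open
#' `(lo, hi]` intervals, and computes prevalence per (land use, level bin,
#' category). Clips with no matching minute are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param presence A `presence_records` data.frame.
#' @param levels A [minute_levels] object.
#' @param sites A `site_records` data.frame.
#' @param config An [analysis_config()] (for `level_bin_edges`).
#' @return A `prevalence_table` with `land_use` and `dba_bin` strata.
#' @export
prevalence_by_level <- function(presence, levels, sites,
                                config = analysis_config()) {
  lv <- data.frame(site_id = levels$site_id, timestamp = levels$timestamp,
                   level = levels$level, stringsAsFactors = FALSE)
  df <- merge(as.data.frame(presence), lv, by = c("site_id", "timestamp"),
              all.x = TRUE)
  n_dropped <- sum(is.na(df$level))
  if (n_dropped == nrow(df)) stop("no clip matches any level minute")
  df <- df[!is.na(df$level), , drop = FALSE]
  edges <- config$level_bin_edges
  df$dba_bin <- as.character(cut(df$level, breaks = c(-Inf, edges, Inf),
                                 right = TRUE))
  df <- merge(df, as.data.frame(sites)[, c("site_id", "land_use")],
              by = "site_id")
  out <- prevalence(df, by = c("land_use", "dba_bin"))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Flag sites within a buffer of a flight path
#'
#' Computes each site's great-circle distance to the nearest point of the
#' flight-path polyline and flags sites within the buffer. Used to report
#' aircraft prevalence separately near/far from the airport approach.
#'
#' @param sites A `site_records` data.frame.
#' @param path data.frame with `lat`, `lon` vertices (>= 2, non-degenerate).
#' @param buffer_m Buffer distance in metres (default 1000).
#' @return `sites` with added `flightpath_dist_m` and `flight_path`
#'   (`"within"` / `"outside"`).
#' @export
flight_path_strata <- function(sites, path, buffer_m = 1000) {
  path <- check_flight_path(path)
  if (all(path$lat == path$lat[1]) && all(path$lon == path$lon[1]))
    stop("degenerate flight path: all vertices identical")
  d <- geosphere::dist2Line(p = cbind(sites$lon, sites$lat),
                            line = cbind(path$lon, path$lat))
  sites <- as.data.frame(sites)
  sites$flightpath_dist_m <- d[, "distance"]
  sites$flight_path <- ifelse(sites$flightpath_dist_m <= buffer_m,
                              "within", "outside")
  sites
}

#' Positive predictive value per category
#'
#' `PPV = 100 * TP / (TP + FP)`, the fraction of predicted presences that a
#' blinded manual labeller confirmed. Undefined (missing) when a category was
#' never predicted.
#'
#' @param counts data.frame with columns `category`, `tp`, `fp` (non-negative
#'   integers).
#' @return `counts` with an added `ppv_pct` column.
#' @export
ppv <- function(counts) {
  stopifnot(all(c("category", "tp", "fp") %in% names(counts)))
  if (any(counts$tp < 0 | counts$fp < 0))
    stop("validation counts must be non-negative")
  counts <- as.data.frame(counts)
  denom <- counts$tp + counts$fp
  counts$ppv_pct <- ifelse(denom > 0, 100 * counts$tp / denom, NA_real_)
  counts
}
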