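## Stratified descriptive statistics, group comparisons, empirical CDFs, and
## the short-term vs long-term representativeness analysis.

#' Median and interquartile range by strata
#'
#' Quartiles use linear interpolation between the closest order statistics
#' (`stats::quantile` type 7), the convention used throughout the package.
#'
#' @param df data.frame of metric rows.
#' @param metric Name of the numeric column to summarize.
#' @param by Character vector of stratum columns (empty = aggregate).
#' @param na.rm Drop missing metric values (default TRUE).
#' @return data.frame with strata, `n`, `q25`, `median`, `q75`.
#' @export
stratified_summary <- function(df, metric, by = character(), na.rm = TRUE) {
  if (!metric %in% names(df)) stop("no column named '", metric, "'")
  miss <- setdiff(by, names(df))
  if (length(miss)) stop("missing stratum column(s): ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(df)
  if (na.rm) dt <- dt[is.finite(dt[[metric]])]
  if (nrow(dt) == 0L) {
    warning("no rows to summarize")
    return(data.frame())
  }
  g <- dt[, {
    x <- .SD[[1]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(n = .N, q25 = q[1], median = q[2], q75 = q[3])
  }, by = by, .SDcols = metric]
  if (length(by)) data.table::setorderv(g, by)
  as.data.frame(g)
}

#' Two-sided Wilcoxon rank-sum comparison of two strata
#'
#' Exact null distribution when both groups have at most 20 observations and
#' there are no ties; otherwise the normal approximation with mid-ranks, tie
#' correction and continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return list with `statistic` (Mann-Whitney U for `a`), `p_value`,
#'   `method` (`"exact"` or `"normal approximation"`).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 20L && length(b) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors with at least 3 complete pairs; returns
#'   `NA` (with a warning) when either variable has zero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Empirical CDFs of minute levels on a dBA grid
#'
#' One step-function CDF per group (e.g. hour band x land use), evaluated on
#' a common grid; each curve is monotone non-decreasing from 0 to 1.
#'
#' @param levels Numeric vector of LAeq_1min values.
#' @param groups Factor/character vector parallel to `levels`.
#' @param grid dBA evaluation grid (default `seq(30, 100, 0.5)`); the grid
#'   is extended to cover the data maximum so every curve reaches 1.
#' @return data.frame with `group`, `dba`, `cdf`.
#' @export
cdf_curves <- function(levels, groups, grid = seq(30, 100, 0.5)) {
  stopifnot(length(levels) == length(groups))
  if (max(levels) > max(grid))
    grid <- c(grid, max(levels))
  sp <- split(levels, groups)
  sp <- sp[lengths(sp) > 0]
  do.call(rbind, lapply(names(sp), function(g) {
    data.frame(group = g, dba = grid, cdf = stats::ecdf(sp[[g]])(grid),
               stringsAsFactors = FALSE)
  }))
}

#' Short-term vs long-term representativeness at fixed sites
#'
#' For each fixed site, samples `n_days` daily LAeq_24hr values without
#' replacement and compares each to the site's yearly average: difference
#' (sampled - yearly, dBA) and percent difference (100 * difference /
#' yearly). The yearly average is by default the energetic mean of the daily
#' LAeq_24hr values (physically consistent); an arithmetic-mean alternative
#' is available. Reports per-site and pooled medians of the signed and
#' absolute quantities; pooled medians are taken over the concatenated
#' per-site sampled differences.
#'
#' @param metrics A `period_metrics` data.frame (needs `site_id`, `date`,
#'   `laeq_24hr`) covering the long-term record of each site.
#' @param n_days Number of random days per site (default 5).
#' @param seed Integer seed; the sampled dates are reproducible given
#'   (seed, site list).
#' @param yearly `"energetic"` (default) or `"arithmetic"` yearly average.
#' @return An object of class `representativeness`: list with `samples`
#'   (per sampled site-day differences), `per_site` and `pooled` medians.
#' @export
representativeness <- function(metrics, n_days = 5, seed = 1,
                               yearly = c("energetic", "arithmetic")) {
  yearly <- match.arg(yearly)
  df <- as.data.frame(metrics)
  df <- df[is.finite(df$laeq_24hr), c("site_id", "date", "laeq_24hr")]
  sites <- sort(unique(df$site_id))
  short <- sites[vapply(sites, function(s) sum(df$site_id == s) < n_days, TRUE)]
  if (length(short))
    stop("fewer than ", n_days, " valid days at site(s): ",
         paste(short, collapse = ", "))
  set.seed(seed)
  samples <- do.call(rbind, lapply(sites, function(s) {
    x <- df[df$site_id == s, ]
    x <- x[order(x$date), ]
    yr <- if (yearly == "energetic") energetic_average(x$laeq_24hr)
          else mean(x$laeq_24hr)
    pick <- x[sample.int(nrow(x), n_days), ]
    data.frame(site_id = s, date = pick$date, laeq_24hr = pick$laeq_24hr,
               yearly_laeq = yr,
               diff_dba = pick$laeq_24hr - yr,
               pct_diff = 100 * (pick$laeq_24hr - yr) / yr,
               stringsAsFactors = FALSE)
  }))
  med4 <- function(d) data.frame(
    median_diff_dba = stats::median(d$diff_dba),
    median_abs_diff_dba = stats::median(abs(d$diff_dba)),
    median_pct_diff = stats::median(d$pct_diff),
    median_abs_pct_diff = stats::median(abs(d$pct_diff)))
  per_site <- do.call(rbind, lapply(split(samples, samples$site_id), med4))
  per_site <- cbind(site_id = rownames(per_site), per_site,
                    stringsAsFactors = FALSE)
  rownames(per_site) <- NULL
  structure(list(samples = samples, per_site = per_site,
                 pooled = med4(samples), n_days = n_days, seed = seed,
                 yearly = yearly),
            class = "representativeness")
}

#' @export
print.representativeness <- function(x, ...) {
  cat(sprintf(
    "<representativeness> %d sites x %d sampled days (%s yearly average)\n",
    nrow(x$per_site), x$n_days, x$yearly))
  cat(sprintf("  pooled median difference     : %+.2f dBA (abs %.2f dBA)\n",
              x$pooled$median_diff_dba, x$pooled$median_abs_diff_dba))
  cat(sprintf("  pooled median pct difference : %+.2f %% (abs %.2f %%)\n",
              x$pooled$median_pct_diff, x$pooled$median_abs_pct_diff))
  invisible(x)
}
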