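#' Descriptive statistics and limit exceedances for daily PM series
#'
#' Summarises each (station, pollutant) series either pooled over all years
#' or per calendar year: observation count, min/max, mean, sample standard
#' deviation (n-1), 5th and 95th percentiles (linear interpolation between
#' order statistics), and, for every supplied limit set, the number and
#' fraction of days strictly over the daily limit plus a flag comparing the
#' (annual or pooled) mean to the annual limit. A day exactly at the limit
#' counts as compliant.
#'
#' Per-year summaries carry a `complete` flag: a year whose data capture is
#' below `completeness` (fraction of calendar days with a valid value) is
#' flagged rather than silently included. Pooled summaries ignore the
#' threshold, matching the convention of multi-year monitoring reports that
#' pool whatever data exist.
#'
#' @param daily A [pm_daily()] table.
#' @param limits List of [limit_set()] objects (default
#'   [default_limit_sets()]).
#' @param by_year Summarise per calendar year (`TRUE`) or pooled (`FALSE`).
#' @param completeness Minimum fraction of calendar days required for a
#'   per-year summary to be flagged complete (default 0.75).
#' @return data.frame with one row per station x pollutant (x year), stat
#'   columns, and `days_over_*`, `frac_over_*`, `annual_over_*` columns per
#'   limit set. Fractions are proportions, not percentages.
#' @export
pm_summary <- function(daily, limits = default_limit_sets(),
                       by_year = FALSE, completeness = 0.75) {
  daily <- pm_daily(daily)
  if (nrow(daily) == 0L) stop("empty daily table")
  stopifnot(is.list(limits), all(vapply(limits, inherits, logical(1), "limit_set")))
  daily$year <- as.integer(format(daily$date, "%Y"))
  groups <- if (by_year) {
    split(daily, list(daily$station_id, daily$pollutant, daily$year), drop = TRUE)
  } else {
    split(daily, list(daily$station_id, daily$pollutant), drop = TRUE)
  }
  rows <- lapply(groups, function(g) {
    v <- g$value
    yr <- if (by_year) g$year[1] else NA_integer_
    complete <- NA
    if (by_year) {
      ndays <- as.integer(as.Date(sprintf("%d-12-31", yr)) -
                            as.Date(sprintf("%d-01-01", yr))) + 1L
      complete <- length(v) >= completeness * ndays
    }
    out <- data.frame(
      station_id = g$station_id[1], pollutant = g$pollutant[1],
      year = yr, complete = complete, n_obs = length(v),
      min = min(v), max = max(v), mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      p5 = unname(stats::quantile(v, 0.05, type = 7)),
      p95 = unname(stats::quantile(v, 0.95, type = 7)),
      stringsAsFactors = FALSE)
    for (ls in limits) {
      dl <- daily_limit(ls, g$pollutant[1])
      al <- annual_limit(ls, g$pollutant[1])
      days <- if (is.na(dl)) NA_integer_ else sum(v > dl)
      out[[paste0("days_over_", ls$name)]] <- days
      out[[paste0("frac_over_", ls$name)]] <- if (is.na(dl)) NA_real_ else days / length(v)
      out[[paste0("annual_over_", ls$name)]] <- if (is.na(al)) NA else mean(v) > al
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$station_id, res$pollutant, res$year), , drop = FALSE]
}

#' Multi-annual monthly climatology
#'
#' Month-of-year mean concentration pooled over all years, per station and
#' pollutant. Months with no observations are reported as `NA`, never
#' zero-filled.
#'
#' @param daily A [pm_daily()] table.
#' @return data.frame with columns station_id, pollutant, month (1-12),
#'   mean, n_obs.
#' @export
monthly_climatology <- function(daily) {
  daily <- pm_daily(daily)
  if (nrow(daily) == 0L) stop("empty daily table")
  daily$month <- as.integer(format(daily$date, "%m"))
  groups <- split(daily, list(daily$station_id, daily$pollutant), drop = TRUE)
  rows <- lapply(groups, function(g) {
    m <- vapply(1:12, function(mo) mean(g$value[g$month == mo]), numeric(1))
    n <- vapply(1:12, function(mo) sum(g$month == mo), integer(1))
    m[n == 0L] <- NA_real_
    data.frame(station_id = g$station_id[1], pollutant = g$pollutant[1],
               month = 1:12, mean = m, n_obs = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$station_id, res$pollutant, res$month), , drop = FALSE]
}

#' Ordinary least squares of daily PM2.5 on PM10
#'
#' Inner-joins the two pollutant series of one station on date and fits
#' PM2.5 = intercept + slope * PM10 by closed-form least squares, reporting
#' the correlation, coefficient of determination, F statistic with its
#' upper-tail significance under F(1, n-2), and the mean daily PM2.5/PM10
#' ratio over pairs with PM10 > 0.
#'
#' @param daily A [pm_daily()] table containing both pollutants for
#'   `station_id` (or for the single station present when `NULL`).
#' @param station_id Station to analyse.
#' @return Object of class `regression_result` with elements slope,
#'   intercept, r, r_squared, f_statistic, f_significance, n, mean_ratio.
#' @export
regress_pm25_on_pm10 <- function(daily, station_id = NULL) {
  daily <- pm_daily(daily)
  if (is.null(station_id)) {
    station_id <- unique(daily$station_id)
    if (length(station_id) != 1L) stop("station_id must be given when the table holds several stations")
  }
  d <- daily[daily$station_id == station_id, ]
  p10 <- d[d$pollutant == "PM10", c("date", "value")]
  p25 <- d[d$pollutant == "PM25", c("date", "value")]
  m <- merge(p10, p25, by = "date", suffixes = c("_pm10", "_pm25"))
  n <- nrow(m)
  if (n < 3L) stop("fewer than 3 paired PM10/PM2.5 dates for station ", station_id)
  x <- m$value_pm10; y <- m$value_pm25
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in PM10 for station ", station_id)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
  r2 <- if (is.na(r)) NA_real_ else r^2
  fstat <- if (is.na(r2) || r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  fsig <- if (is.finite(fstat)) stats::pf(fstat, 1, n - 2, lower.tail = FALSE) else 0
  pos <- x > 0
  structure(list(station_id = station_id, n = n, slope = slope,
                 intercept = intercept, r = r, r_squared = r2,
                 f_statistic = fstat, f_significance = fsig,
                 mean_ratio = mean(y[pos] / x[pos])),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result %s> PM2.5 = %.4f + %.4f * PM10 (n = %d)\n",
              x$station_id, x$intercept, x$slope, x$n))
  cat(sprintf("  r = %.3f, R^2 = %.3f, F-significance = %.3g, mean PM2.5/PM10 ratio = %.3f\n",
              x$r, x$r_squared, x$f_significance, x$mean_ratio))
  invisible(x)
}

#' Estimate an annual PM2.5 mean from a PM10 mean
#'
#' Applies the fixed PM2.5/PM10 conversion factor used for stations that do
#' not measure PM2.5 directly (default 0.7, the regional mean ratio).
#'
#' @param pm10_annual_mean Annual PM10 mean, ug/m3, non-negative.
#' @param factor Conversion factor in (0, 1].
#' @return Estimated PM2.5 annual mean, ug/m3.
#' @export
estimate_pm25_from_pm10 <- function(pm10_annual_mean, factor = 0.7) {
  if (any(pm10_annual_mean < 0)) stop("PM10 mean must be non-negative")
  stopifnot(factor > 0, factor <= 1)
  pm10_annual_mean * factor
}

#' Regional mean of station-level means
#'
#' Unweighted arithmetic mean of station-level pollutant means, the
#' region-wide exposure figure quoted in monitoring reports.
#'
#' @param values Numeric vector of station means (ug/m3).
#' @return Single mean, ug/m3.
#' @export
regional_mean <- function(values) {
  if (length(values) == 0L) stop("no station means supplied")
  if (anyNA(values)) stop("NA station means supplied")
  mean(values)
}
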