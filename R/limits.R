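#' Regulatory limit sets for particulate matter
#'
#' A `limit_set` bundles the annual-mean and daily (24 h) concentration
#' limits for PM10 and PM2.5 under one named standard. Limits that a
#' standard does not regulate are left `NA` (e.g. the Romanian/EU rules set
#' no daily PM2.5 limit).
#'
#' @param name Short identifier for the standard (e.g. `"WHO_2021"`).
#' @param pm10_annual,pm10_daily,pm25_annual,pm25_daily Limits in ug/m3,
#'   or `NA` where the standard has none.
#' @return An object of class `limit_set`.
#' @seealso [default_limit_sets()]
#' @export
limit_set <- function(name, pm10_annual = NA_real_, pm10_daily = NA_real_,
                      pm25_annual = NA_real_, pm25_daily = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lim <- c(pm10_annual = pm10_annual, pm10_daily = pm10_daily,
           pm25_annual = pm25_annual, pm25_daily = pm25_daily)
  lim <- vapply(lim, as.numeric, numeric(1))
  bad <- !is.na(lim) & lim <= 0
  if (any(bad)) {
    stop("limits must be positive where present: ",
         paste(names(lim)[bad], collapse = ", "))
  }
  structure(as.list(c(list(name = name), as.list(lim))), class = "limit_set")
}

#' @export
print.limit_set <- function(x, ...) {
  cat(sprintf("<limit_set '%s'> PM10 annual/daily: %s/%s  PM2.5 annual/daily: %s/%s (ug/m3)\n",
              x$name, format(x$pm10_annual), format(x$pm10_daily),
              format(x$pm25_annual), format(x$pm25_daily)))
  invisible(x)
}

#' Built-in air-quality limit sets
#'
#' Returns the limit sets used throughout the package: the Romanian/EU
#' standard (Law 104/2011, transposing the EU ambient air directives) with
#' both the pre-2020 PM2.5 annual limit (25 ug/m3, `RO_EU`) and the 2020
#' target (20 ug/m3, `RO_EU_2020`), and the WHO 2005 and 2021 air-quality
#' guideline values.
#'
#' @return Named list of [limit_set()] objects.
#' @export
default_limit_sets <- function() {
  list(
    RO_EU      = limit_set("RO_EU",      pm10_annual = 40, pm10_daily = 50,
                           pm25_annual = 25),
    RO_EU_2020 = limit_set("RO_EU_2020", pm10_annual = 40, pm10_daily = 50,
                           pm25_annual = 20),
    WHO_2005   = limit_set("WHO_2005",   pm10_annual = 20, pm10_daily = 50,
                           pm25_annual = 10, pm25_daily = 25),
    WHO_2021   = limit_set("WHO_2021",   pm10_annual = 15, pm10_daily = 45,
                           pm25_annual = 5,  pm25_daily = 15)
  )
}

# limit lookup by pollutant code ("PM10"/"PM25")
daily_limit <- function(ls, pollutant) {
  if (identical(pollutant, "PM10")) ls$pm10_daily else ls$pm25_daily
}

annual_limit <- function(ls, pollutant) {
  if (identical(pollutant, "PM10")) ls$pm10_annual else ls$pm25_annual
}
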