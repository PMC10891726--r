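#' @title Reading and writing the tabular inputs
#' @description Readers validate aggressively: a malformed row is reported
#'   with its line number rather than silently dropped, negative
#'   concentrations and unknown pollutant codes are errors, and duplicate
#'   (station, date, pollutant) observations abort with the offending key.
#'   Silent column drift is the main ingestion hazard in routine
#'   air-quality exports, so nothing is coerced quietly.
#' @name ingest
NULL

POLLUTANTS <- c("PM10", "PM25")
CAUSES <- c("all_nonexternal", "cvd")

#' Validate a daily concentration table
#'
#' The long daily table holds one row per (station, pollutant, date)
#' observation: columns `station_id`, `date` (class `Date`), `pollutant`
#' (`"PM10"` or `"PM25"`) and `value` (ug/m3, finite and non-negative).
#' Gaps in the calendar are simply absent rows.
#'
#' @param x A data.frame with the columns above.
#' @return `x` with class `pm_daily` prepended, invisibly validated.
#' @export
pm_daily <- function(x) {
  need <- c("station_id", "date", "pollutant", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  if (!inherits(x$date, "Date")) x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable dates in daily table")
  bad_pol <- setdiff(unique(x$pollutant), POLLUTANTS)
  if (length(bad_pol)) {
    stop("unknown pollutant code(s): ", paste(bad_pol, collapse = ", "),
         " (expected PM10/PM25)")
  }
  if (anyNA(x$value) || any(!is.finite(x$value))) {
    stop("non-finite concentration values in daily table")
  }
  if (any(x$value < 0)) stop("negative concentration values in daily table")
  key <- paste(x$station_id, x$pollutant, x$date)
  if (anyDuplicated(key)) {
    stop("duplicate (station, pollutant, date) observation(s): ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "))
  }
  class(x) <- c("pm_daily", "data.frame")
  x
}

#' Read a daily concentration CSV
#'
#' Expected columns: `station_id,date,pollutant,value_ugm3`; dates ISO-8601;
#' comma separated, `.` decimal, UTF-8, header mandatory.
#'
#' @param path Path to the CSV file.
#' @return A validated [pm_daily()] data.frame.
#' @export
read_daily_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("station_id", "date", "pollutant", "value_ugm3")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("daily CSV missing column(s): ", paste(miss, collapse = ", "))
  # line numbers in messages count the header as line 1
  line <- seq_len(nrow(raw)) + 1L
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  value <- suppressWarnings(as.numeric(raw$value_ugm3))
  problems <- character(0)
  bad <- is.na(date)
  if (any(bad)) problems <- c(problems, paste0("line ", line[bad], ": bad date '", raw$date[bad], "'"))
  bad <- is.na(value)
  if (any(bad)) problems <- c(problems, paste0("line ", line[bad], ": bad value '", raw$value_ugm3[bad], "'"))
  bad <- !is.na(value) & value < 0
  if (any(bad)) problems <- c(problems, paste0("line ", line[bad], ": negative value ", raw$value_ugm3[bad]))
  bad <- !raw$pollutant %in% POLLUTANTS
  if (any(bad)) problems <- c(problems, paste0("line ", line[bad], ": unknown pollutant '", raw$pollutant[bad], "'"))
  if (length(problems)) {
    stop("invalid rows in ", path, ":\n  ",
         paste(utils::head(problems, 10), collapse = "\n  "))
  }
  key <- paste(raw$station_id, raw$pollutant, raw$date)
  if (anyDuplicated(key)) {
    d <- unique(key[duplicated(key)])
    stop("duplicate (station, pollutant, date) in ", path, ": ",
         paste(utils::head(d, 5), collapse = "; "))
  }
  pm_daily(data.frame(station_id = raw$station_id, date = date,
                      pollutant = raw$pollutant, value = value,
                      stringsAsFactors = FALSE))
}

#' Write a daily concentration CSV
#' @param daily A [pm_daily()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(daily, path) {
  daily <- pm_daily(daily)
  out <- data.frame(station_id = daily$station_id,
                    date = format(daily$date, "%Y-%m-%d"),
                    pollutant = daily$pollutant,
                    value_ugm3 = daily$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read station metadata
#'
#' Columns: `station_id,county,site_type,elevation_m,lon,lat,measures_pm25`.
#' `site_type` must be one of urban, suburban, rural, industrial;
#' `measures_pm25` is TRUE/FALSE.
#'
#' @param path Path to the stations CSV.
#' @return data.frame of station records; `station_id` is checked unique.
#' @export
read_stations_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "county", "site_type", "elevation_m", "lon", "lat",
            "measures_pm25")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("stations CSV missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$station_id)) {
    stop("duplicate station_id: ",
         paste(unique(x$station_id[duplicated(x$station_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(x$site_type), c("urban", "suburban", "rural", "industrial"))
  if (length(bad)) stop("unknown site_type: ", paste(bad, collapse = ", "))
  x$measures_pm25 <- as.logical(x$measures_pm25)
  if (anyNA(x$measures_pm25)) stop("measures_pm25 must be TRUE/FALSE")
  x[need]
}

#' Write station metadata
#' @param stations data.frame as returned by [read_stations_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stations_csv <- function(stations, path) {
  utils::write.csv(stations[c("station_id", "county", "site_type",
                              "elevation_m", "lon", "lat", "measures_pm25")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shared check: age groups form a contiguous ascending partition with one
# terminal open-ended group (age_width NA)
check_age_groups <- function(age_start, age_width, what) {
  o <- order(age_start)
  age_start <- age_start[o]; age_width <- age_width[o]
  n <- length(age_start)
  if (n < 1L) stop(what, ": no age groups")
  open <- is.na(age_width)
  if (sum(open) != 1L || !open[n]) {
    stop(what, ": exactly one open-ended age group is required, and it must be the oldest")
  }
  if (n > 1L) {
    expected <- age_start[-n] + age_width[-n]
    if (any(expected != age_start[-1L])) {
      stop(what, ": age groups must be contiguous and non-overlapping")
    }
  }
  invisible(TRUE)
}

#' Read a population table
#'
#' Columns: `area,age_start,age_width,persons`; an empty `age_width` marks
#' the open-ended terminal group. Per area, the age groups must form a
#' contiguous ascending partition.
#'
#' @param path Path to the population CSV.
#' @return data.frame with columns area, age_start, age_width (NA = open),
#'   persons.
#' @export
read_population_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area", "age_start", "age_width", "persons")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("population CSV missing column(s): ", paste(miss, collapse = ", "))
  x$age_width <- suppressWarnings(as.numeric(x$age_width))
  x$age_start <- as.numeric(x$age_start)
  x$persons <- as.numeric(x$persons)
  if (anyNA(x$persons) || any(x$persons < 0)) stop("persons must be non-negative")
  for (a in unique(x$area)) {
    sub <- x[x$area == a, ]
    check_age_groups(sub$age_start, sub$age_width, paste0("population (area ", a, ")"))
  }
  x[need]
}

#' Write a population table
#' @param pop data.frame as returned by [read_population_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  out <- pop[c("area", "age_start", "age_width", "persons")]
  out$age_width <- ifelse(is.na(out$age_width), "", out$age_width)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deaths table
#'
#' Columns: `area,year,age_start,age_width,cause,deaths`; `cause` is
#' `all_nonexternal` or `cvd`. Where both causes are present for the same
#' stratum, cvd deaths may not exceed all-cause deaths.
#'
#' @param path Path to the deaths CSV.
#' @return data.frame with columns area, year, age_start, age_width, cause,
#'   deaths.
#' @export
read_deaths_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area", "year", "age_start", "age_width", "cause", "deaths")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("deaths CSV missing column(s): ", paste(miss, collapse = ", "))
  x$age_width <- suppressWarnings(as.numeric(x$age_width))
  bad <- setdiff(unique(x$cause), CAUSES)
  if (length(bad)) stop("unknown cause: ", paste(bad, collapse = ", "))
  x$deaths <- as.numeric(x$deaths)
  if (anyNA(x$deaths) || any(x$deaths < 0)) stop("deaths must be non-negative")
  wide <- merge(
    x[x$cause == "all_nonexternal", c("area", "year", "age_start", "deaths")],
    x[x$cause == "cvd", c("area", "year", "age_start", "deaths")],
    by = c("area", "year", "age_start"), suffixes = c("_all", "_cvd"))
  if (nrow(wide) && any(wide$deaths_cvd > wide$deaths_all)) {
    i <- which(wide$deaths_cvd > wide$deaths_all)[1]
    stop("cvd deaths exceed all-cause deaths for area ", wide$area[i],
         ", year ", wide$year[i], ", age ", wide$age_start[i])
  }
  x[need]
}

#' Write a deaths table
#' @param deaths data.frame as returned by [read_deaths_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deaths_csv <- function(deaths, path) {
  out <- deaths[c("area", "year", "age_start", "age_width", "cause", "deaths")]
  out$age_width <- ifelse(is.na(out$age_width), "", out$age_width)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
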