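#' Configuration of the synthetic monitoring-and-registry data generator
#'
#' The generator emulates the statistical regime of a regional PM
#' monitoring network and its vital statistics: around twenty stations over
#' a decade of daily data (default 2012 start, 10 years), station-level
#' multi-annual PM10 means drawn uniformly in 9-31 ug/m3, a single annual
#' sinusoid with winter peak for seasonality, uniform-at-random gaps, a
#' PM2.5/PM10 target ratio of 0.7, populations aged 30 to an open-ended 80+
#' in ten-year groups, and Poisson death counts whose expectation carries a
#' planted log-linear concentration-response signal
#' `P * rate * exp(true_beta * (x - baseline_conc))` so that downstream
#' estimators can be tested for parameter recovery. A configurable fraction
#' of deaths (default 0.53) is labelled cardiovascular.
#'
#' @param n_stations Number of monitoring stations.
#' @param n_years Number of calendar years of daily data.
#' @param start_year First calendar year.
#' @param pm10_annual_mean_range Range (ug/m3) the station-level annual
#'   means are drawn from.
#' @param seasonal_amplitude Amplitude of the annual sinusoid, ug/m3.
#' @param pm_ratio Target PM2.5/PM10 ratio in (0, 1].
#' @param missing_fraction Fraction of days removed at random, in [0, 1).
#' @param noise_sd Standard deviation of the additive daily noise, ug/m3.
#' @param true_beta Planted concentration-response coefficient, per ug/m3.
#' @param baseline_conc Baseline concentration X0 of the planted signal.
#' @param age_groups data.frame with columns age_start, age_width (NA for
#'   the open-ended terminal group).
#' @param base_population Persons aged 30+ per area.
#' @param base_death_rate Baseline death rate (deaths per person-year) per
#'   age group, same length as `age_groups` rows.
#' @param cvd_fraction Expected share of deaths labelled cardiovascular.
#' @param pm25_station_fraction Share of stations measuring PM2.5.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_stations = 22, n_years = 10, start_year = 2012,
                             pm10_annual_mean_range = c(9, 31),
                             seasonal_amplitude = 8, pm_ratio = 0.7,
                             missing_fraction = 0.1, noise_sd = 6,
                             true_beta = 0.005826, baseline_conc = 10,
                             age_groups = data.frame(
                               age_start = c(30, 40, 50, 60, 70, 80),
                               age_width = c(10, 10, 10, 10, 10, NA)),
                             base_population = 340000,
                             base_death_rate = c(0.002, 0.004, 0.010,
                                                 0.022, 0.050, 0.130),
                             cvd_fraction = 0.53,
                             pm25_station_fraction = 0.25,
                             seed = 1L) {
  stopifnot(n_stations >= 1, n_years >= 1,
            length(pm10_annual_mean_range) == 2,
            diff(pm10_annual_mean_range) >= 0,
            pm10_annual_mean_range[1] >= 0,
            seasonal_amplitude >= 0, noise_sd >= 0,
            baseline_conc >= 0, base_population > 0,
            cvd_fraction >= 0, cvd_fraction <= 1,
            pm25_station_fraction > 0, pm25_station_fraction <= 1)
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  if (pm_ratio <= 0 || pm_ratio > 1) stop("pm_ratio must be in (0, 1]")
  check_age_groups(age_groups$age_start, age_groups$age_width, "age_groups")
  if (length(base_death_rate) != nrow(age_groups)) {
    stop("base_death_rate must have one entry per age group")
  }
  if (any(base_death_rate <= 0)) stop("base_death_rate must be positive")
  structure(list(n_stations = n_stations, n_years = n_years,
                 start_year = start_year,
                 pm10_annual_mean_range = pm10_annual_mean_range,
                 seasonal_amplitude = seasonal_amplitude, pm_ratio = pm_ratio,
                 missing_fraction = missing_fraction, noise_sd = noise_sd,
                 true_beta = true_beta, baseline_conc = baseline_conc,
                 age_groups = age_groups, base_population = base_population,
                 base_death_rate = base_death_rate,
                 cvd_fraction = cvd_fraction,
                 pm25_station_fraction = pm25_station_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# run code under a derived seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic county polygons
#'
#' A rectangular region split into a grid of equal rectangular counties, in
#' planar km coordinates. Adequate as a stand-in for administrative
#' boundaries in tests and demos: polygons are valid, disjoint and cover
#' the region.
#'
#' @param n_counties Number of counties (default 6).
#' @param width_km,height_km Region extent.
#' @return A `region_polygons` object with counties named
#'   `county_1 ... county_n`.
#' @export
synthetic_region <- function(n_counties = 6, width_km = 240, height_km = 160) {
  stopifnot(n_counties >= 1)
  nc <- ceiling(sqrt(n_counties))
  nr <- ceiling(n_counties / nc)
  w <- width_km / nc; h <- height_km / nr
  parts <- list()
  k <- 0
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (k >= n_counties) break
      k <- k + 1
      x0 <- (c - 1) * w; y0 <- (r - 1) * h
      parts[[paste0("county_", k)]] <-
        cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
    }
  }
  region_polygons(parts)
}

#' Generate synthetic station records
#'
#' Station locations are sampled uniformly inside the region (rejection
#' sampling over the bounding box), assigned to the county containing them,
#' and a configurable subset is marked as measuring PM2.5 (at least one).
#'
#' @param cfg A [synthetic_config()].
#' @param region A `region_polygons` object.
#' @return data.frame in the stations-CSV schema: station_id, county,
#'   site_type, elevation_m, lon, lat, measures_pm25.
#' @export
generate_stations <- function(cfg, region) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(region, "region_polygons"))
  areas <- region_areas(region)
  if (any(areas <= 0)) stop("degenerate region polygon (zero area)")
  all_xy <- do.call(rbind, lapply(region, function(f) do.call(rbind, f$parts)))
  nms <- region_names(region)
  with_seed(cfg$seed + 1L, {
    xs <- numeric(0); ys <- numeric(0); cty <- character(0)
    while (length(xs) < cfg$n_stations) {
      m <- 4L * (cfg$n_stations - length(xs)) + 16L
      px <- stats::runif(m, min(all_xy[, 1]), max(all_xy[, 1]))
      py <- stats::runif(m, min(all_xy[, 2]), max(all_xy[, 2]))
      hit <- rep(NA_character_, m)
      for (nm in nms) {
        inside <- is.na(hit) & region_contains(region, nm, px, py)
        hit[inside] <- nm
      }
      keep <- !is.na(hit)
      xs <- c(xs, px[keep]); ys <- c(ys, py[keep]); cty <- c(cty, hit[keep])
    }
    xs <- xs[seq_len(cfg$n_stations)]; ys <- ys[seq_len(cfg$n_stations)]
    cty <- cty[seq_len(cfg$n_stations)]
    k <- max(1L, round(cfg$pm25_station_fraction * cfg$n_stations))
    pm25 <- seq_len(cfg$n_stations) %in% sample(cfg$n_stations, k)
    data.frame(
      station_id = sprintf("ST%02d", seq_len(cfg$n_stations)),
      county = cty,
      site_type = sample(c("urban", "suburban", "rural", "industrial"),
                         cfg$n_stations, replace = TRUE,
                         prob = c(0.5, 0.2, 0.1, 0.2)),
      elevation_m = round(stats::runif(cfg$n_stations, 200, 1200)),
      lon = xs, lat = ys, measures_pm25 = pm25,
      stringsAsFactors = FALSE)
  })
}

#' Generate synthetic daily PM series
#'
#' For every station, a daily PM10 series over the configured calendar
#' years: a station-level annual mean drawn uniformly from
#' `pm10_annual_mean_range`, plus an annual sinusoid peaking in mid-January
#' (winter maximum, summer minimum), plus Gaussian noise, clipped at zero,
#' with `missing_fraction` of days removed at random. Stations flagged
#' `measures_pm25` additionally get a PM2.5 series equal to
#' `pm_ratio * PM10` plus independent noise (sd scaled by the ratio),
#' clipped at zero, with its own random gaps.
#'
#' @param cfg A [synthetic_config()].
#' @param stations Station records from [generate_stations()].
#' @return A [pm_daily()] table.
#' @export
generate_daily_pm <- function(cfg, stations) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$start_year)),
               as.Date(sprintf("%d-12-31", cfg$start_year + cfg$n_years - 1)),
               by = "day")
  doy <- as.numeric(format(dates, "%j"))
  seasonal <- cfg$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  nd <- length(dates)
  with_seed(cfg$seed + 2L, {
    out <- vector("list", 2L * nrow(stations))
    for (i in seq_len(nrow(stations))) {
      am <- stats::runif(1, cfg$pm10_annual_mean_range[1],
                         cfg$pm10_annual_mean_range[2])
      pm10 <- pmax(0, am + seasonal + stats::rnorm(nd, 0, cfg$noise_sd))
      drop10 <- sample(nd, floor(cfg$missing_fraction * nd))
      keep10 <- setdiff(seq_len(nd), drop10)
      out[[2L * i - 1L]] <- data.frame(
        station_id = stations$station_id[i], date = dates[keep10],
        pollutant = "PM10", value = pm10[keep10], stringsAsFactors = FALSE)
      if (stations$measures_pm25[i]) {
        pm25 <- pmax(0, cfg$pm_ratio * pm10 +
                       stats::rnorm(nd, 0, cfg$noise_sd * cfg$pm_ratio))
        drop25 <- sample(nd, floor(cfg$missing_fraction * nd))
        keep25 <- setdiff(seq_len(nd), drop25)
        out[[2L * i]] <- data.frame(
          station_id = stations$station_id[i], date = dates[keep25],
          pollutant = "PM25", value = pm25[keep25], stringsAsFactors = FALSE)
      }
    }
    pm_daily(do.call(rbind, out[!vapply(out, is.null, logical(1))]))
  })
}

#' Generate synthetic populations and death counts
#'
#' Per area and age group: a fixed population (the configured base
#' population split across groups with geometrically declining shares) and,
#' per calendar year, all-cause (non-external) deaths drawn from a Poisson
#' law with mean `P * base_death_rate * exp(true_beta * (x - baseline))`
#' where x is the area's annual mean exposure — the planted
#' concentration-response signal. Cardiovascular deaths are a binomial
#' thinning of the all-cause count at `cvd_fraction`.
#'
#' @param cfg A [synthetic_config()].
#' @param areas data.frame with columns `area` and `exposure` (annual mean
#'   concentration, ug/m3) per area.
#' @return list with elements `population` and `deaths` in the ingest CSV
#'   schemas.
#' @export
generate_population_and_deaths <- function(cfg, areas) {
  stopifnot(inherits(cfg, "synthetic_config"),
            all(c("area", "exposure") %in% names(areas)))
  if (anyNA(areas$exposure)) {
    stop("missing exposure for area(s): ",
         paste(areas$area[is.na(areas$exposure)], collapse = ", "))
  }
  ng <- nrow(cfg$age_groups)
  share <- exp(-0.25 * (seq_len(ng) - 1))
  share <- share / sum(share)
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  with_seed(cfg$seed + 3L, {
    pop <- do.call(rbind, lapply(seq_len(nrow(areas)), function(i) {
      data.frame(area = areas$area[i],
                 age_start = cfg$age_groups$age_start,
                 age_width = cfg$age_groups$age_width,
                 persons = round(cfg$base_population * share),
                 stringsAsFactors = FALSE)
    }))
    dth <- do.call(rbind, lapply(seq_len(nrow(areas)), function(i) {
      lam <- pop$persons[pop$area == areas$area[i]] * cfg$base_death_rate *
        exp(cfg$true_beta * (areas$exposure[i] - cfg$baseline_conc))
      do.call(rbind, lapply(years, function(y) {
        d_all <- stats::rpois(ng, lam)
        d_cvd <- stats::rbinom(ng, d_all, cfg$cvd_fraction)
        data.frame(area = rep(areas$area[i], 2L * ng),
                   year = y,
                   age_start = rep(cfg$age_groups$age_start, 2),
                   age_width = rep(cfg$age_groups$age_width, 2),
                   cause = rep(c("all_nonexternal", "cvd"), each = ng),
                   deaths = c(d_all, d_cvd),
                   stringsAsFactors = FALSE)
      }))
    }))
    list(population = pop, deaths = dth)
  })
}
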