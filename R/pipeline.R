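#' Configuration of a full pipeline run
#'
#' Bundles everything one end-to-end analysis needs: either a
#' [synthetic_config()] or paths to the five input files, the limit sets,
#' the concentration-response presets per endpoint/horizon, the long-term
#' scenarios, the baseline concentration X0, the annual completeness
#' threshold, the PM2.5/PM10 conversion factor for stations without PM2.5,
#' the output directory and the seed. All randomness in a run flows from
#' this seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param inputs Named list of paths (`daily`, `stations`, `population`,
#'   `deaths`, `region`) when not synthetic.
#' @param limits List of [limit_set()] objects.
#' @param preset_short,preset_long_all,preset_long_cvd Names from
#'   [risk_presets()] for the short-term and the two long-term endpoints.
#' @param scenarios Non-empty list of [scenario()] objects.
#' @param x0 Baseline concentration, ug/m3.
#' @param completeness Annual data-capture threshold in (0, 1].
#' @param pm_ratio PM2.5/PM10 conversion factor for unmeasured stations.
#' @param min_pm25_obs Minimum PM2.5 observations for a station's own
#'   series to be used instead of the conversion (default 365).
#' @param crs Coordinate handling for [thiessen_weights()].
#' @param seed Integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, synthetic = NULL, inputs = NULL,
                       limits = default_limit_sets(),
                       preset_short = "pm10_short_all",
                       preset_long_all = "pm25_long_all",
                       preset_long_cvd = "pm25_long_cvd",
                       scenarios = list(scenario("decrease_by", 5),
                                        scenario("decrease_to", 10)),
                       x0 = 10, completeness = 0.75, pm_ratio = 0.7,
                       min_pm25_obs = 365, crs = "auto", seed = 1L) {
  if (is.null(synthetic) && is.null(inputs)) {
    stop("either `synthetic` or `inputs` must be given")
  }
  if (!is.null(inputs)) {
    need <- c("daily", "stations", "population", "deaths", "region")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
  }
  known <- risk_presets()$preset
  for (p in c(preset_short, preset_long_all, preset_long_cvd)) {
    if (!p %in% known) stop("unknown risk preset '", p, "'")
  }
  if (length(scenarios) == 0L) stop("scenario list must be non-empty")
  stopifnot(all(vapply(scenarios, inherits, logical(1), "scenario")),
            x0 >= 0, completeness > 0, completeness <= 1,
            pm_ratio > 0, pm_ratio <= 1)
  structure(list(out_dir = out_dir, synthetic = synthetic, inputs = inputs,
                 limits = limits, preset_short = preset_short,
                 preset_long_all = preset_long_all,
                 preset_long_cvd = preset_long_cvd, scenarios = scenarios,
                 x0 = x0, completeness = completeness, pm_ratio = pm_ratio,
                 min_pm25_obs = min_pm25_obs, crs = crs,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Mirrors [run_config()]: top-level keys `out_dir`, `seed`, `x0`,
#' `completeness`, `pm_ratio`, `crs`, `presets` (`short`, `long_all`,
#' `long_cvd`), `scenarios` (list of `{mode, amount}`), `limits` (names of
#' built-in sets), and either `synthetic` (fields of [synthetic_config()])
#' or `inputs` (the five paths).
#'
#' @param path Path to a YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A [run_config()] object.
#' @export
load_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  args$out_dir <- if (!is.null(out_dir)) out_dir else y$out_dir
  if (is.null(args$out_dir)) stop("config must set out_dir")
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    if (!is.null(s$age_groups)) s$age_groups <- as.data.frame(s$age_groups)
    if (!is.null(s$pm10_annual_mean_range)) {
      s$pm10_annual_mean_range <- unlist(s$pm10_annual_mean_range)
    }
    if (!is.null(s$base_death_rate)) s$base_death_rate <- unlist(s$base_death_rate)
    args$synthetic <- do.call(synthetic_config, s)
  }
  if (!is.null(y$inputs)) args$inputs <- y$inputs
  if (!is.null(y$limits)) {
    all_sets <- default_limit_sets()
    bad <- setdiff(unlist(y$limits), names(all_sets))
    if (length(bad)) stop("unknown limit set(s): ", paste(bad, collapse = ", "))
    args$limits <- all_sets[unlist(y$limits)]
  }
  if (!is.null(y$presets)) {
    if (!is.null(y$presets$short)) args$preset_short <- y$presets$short
    if (!is.null(y$presets$long_all)) args$preset_long_all <- y$presets$long_all
    if (!is.null(y$presets$long_cvd)) args$preset_long_cvd <- y$presets$long_cvd
  }
  if (!is.null(y$scenarios)) {
    args$scenarios <- lapply(y$scenarios, function(s) scenario(s$mode, s$amount))
  }
  for (k in c("x0", "completeness", "pm_ratio", "min_pm25_obs", "crs", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

# stage wrapper: any error is re-signalled with the stage name attached
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes every stage against the configured inputs (generating and
#' round-tripping synthetic inputs through the CSV/GeoJSON readers when
#' `synthetic` is configured) and writes: pooled and per-year summaries,
#' monthly climatology, the PM2.5~PM10 regression table, station Thiessen
#' weights (CSV + GeoJSON) and allocated deaths, the short-term risk table
#' with its station RR summary, the long-term HIA table, and a run log plus
#' a JSON manifest recording every parameter. Stations without their own
#' PM2.5 series are assessed through the configured PM2.5/PM10 conversion
#' factor, and the log says so per station.
#'
#' @param config A [run_config()] object.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return Invisibly, the manifest (named list of output paths).
#' @export
run_full <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  note("pmhia %s | R %s | seed %d", as.character(utils::packageVersion("pmhia")),
       paste(R.version$major, R.version$minor, sep = "."), config$seed)

  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    idir <- file.path(out, "inputs")
    dir.create(idir, showWarnings = FALSE)
    run_stage("synthetic", {
      region0 <- synthetic_region()
      stations0 <- generate_stations(syn, region0)
      daily0 <- generate_daily_pm(syn, stations0)
      exposure <- synthetic_exposures(daily0, stations0, region0,
                                      syn$pm_ratio)
      pd <- generate_population_and_deaths(syn, exposure)
      write_region_geojson(region0, file.path(idir, "region.geojson"))
      write_stations_csv(stations0, file.path(idir, "stations.csv"))
      write_daily_csv(daily0, file.path(idir, "daily.csv"))
      write_population_csv(pd$population, file.path(idir, "population.csv"))
      write_deaths_csv(pd$deaths, file.path(idir, "deaths.csv"))
      note("synthetic inputs written to %s (stations: %d, daily rows: %d)",
           idir, nrow(stations0), nrow(daily0))
    })
    paths <- list(daily = file.path(idir, "daily.csv"),
                  stations = file.path(idir, "stations.csv"),
                  population = file.path(idir, "population.csv"),
                  deaths = file.path(idir, "deaths.csv"),
                  region = file.path(idir, "region.geojson"))
  } else {
    paths <- config$inputs
  }
  run_stage("ingest", {
    daily <- read_daily_csv(paths$daily)
    stations <- read_stations_csv(paths$stations)
    population <- read_population_csv(paths$population)
    deaths <- read_deaths_csv(paths$deaths)
    region <- read_region_geojson(paths$region)
    note("ingested %d daily observations, %d stations, %d counties",
         nrow(daily), nrow(stations), length(region))
  })

  manifest <- list()
  wr <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE)
    manifest[[sub("\\.csv$", "", name)]] <<- p
    p
  }

  # -- descriptive statistics ----------------------------------------------
  run_stage("pm_stats", {
    wr(pm_summary(daily, config$limits, by_year = FALSE), "summary_pooled.csv")
    wr(pm_summary(daily, config$limits, by_year = TRUE,
                  completeness = config$completeness), "summary_annual.csv")
    wr(monthly_climatology(daily), "monthly_climatology.csv")
  })

  # -- PM2.5 ~ PM10 regression ----------------------------------------------
  run_stage("regression", {
    regs <- list()
    for (sid in unique(stations$station_id)) {
      d <- daily[daily$station_id == sid, ]
      n_pairs <- length(intersect(d$date[d$pollutant == "PM10"],
                                  d$date[d$pollutant == "PM25"]))
      if (n_pairs >= 3L) {
        r <- regress_pm25_on_pm10(daily, sid)
        regs[[sid]] <- data.frame(station_id = sid, n = r$n, slope = r$slope,
                                  intercept = r$intercept, r = r$r,
                                  r_squared = r$r_squared,
                                  f_significance = r$f_significance,
                                  mean_ratio = r$mean_ratio)
      }
    }
    reg_tab <- if (length(regs)) do.call(rbind, regs) else
      data.frame(station_id = character(0), n = integer(0), slope = numeric(0),
                 intercept = numeric(0), r = numeric(0), r_squared = numeric(0),
                 f_significance = numeric(0), mean_ratio = numeric(0))
    rownames(reg_tab) <- NULL
    wr(reg_tab, "regression.csv")
    note("regression fitted for %d station(s)", nrow(reg_tab))
  })

  # -- spatial allocation ---------------------------------------------------
  run_stage("spatial_alloc", {
    weights <- thiessen_weights(stations, region, crs = config$crs)
    wr(as.data.frame(weights)[c("station_id", "county", "area", "weight")],
       "station_weights.csv")
    gj <- file.path(out, "station_cells.geojson")
    write_weights_geojson(weights, gj)
    manifest$station_cells <- gj
    station_deaths <- allocate_deaths(weights, deaths)
    wr(station_deaths, "station_deaths.csv")
    station_pop <- allocate_counts(weights, population, "persons")
    note("allocated deaths across %d station cells", nrow(weights))
  })

  pooled <- pm_summary(daily, config$limits, by_year = FALSE)

  # -- short-term risk ------------------------------------------------------
  run_stage("risk_core", {
    params_s <- risk_params_preset(config$preset_short, baseline = config$x0)
    rows <- list()
    for (sid in unique(stations$station_id)) {
      p <- pooled[pooled$station_id == sid & pooled$pollutant == params_s$pollutant, ]
      if (nrow(p) == 0L) {
        note("short-term risk: %s skipped (no %s data)", sid, params_s$pollutant)
        next
      }
      sd_tab <- station_deaths[station_deaths$station_id == sid &
                                 station_deaths$cause == "all_nonexternal", ]
      n_total <- sum(sd_tab$deaths) / length(unique(sd_tab$year))
      rr <- relative_risk(p$mean, params_s)
      ad <- attributable_deaths(rr$rr, n_total)
      rows[[sid]] <- data.frame(
        unit = sid, endpoint = params_s$endpoint, horizon = params_s$horizon,
        x = p$mean,
        rr_low = rr$rr_low, rr = rr$rr, rr_high = rr$rr_high,
        af = ad$af, n_total = n_total,
        n_assigned_low = if (is.na(rr$rr_low)) NA_real_ else
          attributable_deaths(rr$rr_low, n_total)$n_assigned,
        n_assigned = ad$n_assigned,
        n_assigned_high = if (is.na(rr$rr_high)) NA_real_ else
          attributable_deaths(rr$rr_high, n_total)$n_assigned)
    }
    risk_tab <- do.call(rbind, rows)
    rownames(risk_tab) <- NULL
    wr(risk_tab, "risk_short_term.csv")
    if (nrow(risk_tab) >= 2L) {
      s <- station_rr_summary(risk_tab$rr)
      wr(data.frame(statistic = c("mean", "median", "sd", "se", "min", "max",
                                  "count", "ci_halfwidth", "ci_lower", "ci_upper"),
                    value = c(s$mean, s$median, s$sd, s$se, s$min, s$max,
                              s$count, s$ci_halfwidth, s$ci_lower, s$ci_upper)),
         "rr_summary.csv")
    }
  })

  # -- long-term HIA --------------------------------------------------------
  run_stage("life_table", {
    params_all <- risk_params_preset(config$preset_long_all, baseline = config$x0)
    params_cvd <- risk_params_preset(config$preset_long_cvd, baseline = config$x0)
    rows <- list()
    for (sid in unique(stations$station_id)) {
      p25 <- pooled[pooled$station_id == sid & pooled$pollutant == "PM25", ]
      p10 <- pooled[pooled$station_id == sid & pooled$pollutant == "PM10", ]
      if (nrow(p25) == 1L && p25$n_obs >= config$min_pm25_obs) {
        x25 <- p25$mean
        note("long-term HIA: %s uses its measured PM2.5 mean (%.2f ug/m3)", sid, x25)
      } else if (nrow(p10) == 1L) {
        x25 <- estimate_pm25_from_pm10(p10$mean, config$pm_ratio)
        note("long-term HIA: %s has insufficient PM2.5 data; PM2.5 estimated from PM10 via factor %.2f (%.2f ug/m3)",
             sid, config$pm_ratio, x25)
      } else {
        note("long-term HIA: %s skipped (no usable PM data)", sid)
        next
      }
      spop <- station_pop[station_pop$station_id == sid, ]
      for (ep in c("all_nonexternal", "cvd")) {
        params <- if (ep == "cvd") params_cvd else params_all
        sd_tab <- station_deaths[station_deaths$station_id == sid &
                                   station_deaths$cause == ep, ]
        if (nrow(sd_tab) == 0L) next
        dmean <- tapply(sd_tab$deaths, sd_tab$age_start, mean)
        ages <- as.numeric(names(dmean))
        o <- order(ages)
        ages <- ages[o]; dmean <- dmean[o]
        idx <- match(ages, spop$age_start)
        if (dmean[length(dmean)] <= 0) {
          note("long-term HIA: %s/%s skipped (no deaths in the open age group)", sid, ep)
          next
        }
        for (scn in config$scenarios) {
          rows[[length(rows) + 1L]] <- run_hia(
            age_start = ages, width = spop$age_width[idx],
            population = spop$persons[idx], deaths = as.numeric(dmean),
            x_current = x25, params = params, scn = scn, unit = sid)
        }
      }
    }
    hia_tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(unit = character(0))
    rownames(hia_tab) <- NULL
    wr(as.data.frame(hia_tab), "hia_long_term.csv")
    note("long-term HIA computed for %d (station, endpoint, scenario) rows",
         nrow(hia_tab))
  })

  # -- log and manifest -----------------------------------------------------
  log_path <- file.path(out, "run_log.txt")
  writeLines(log_lines, log_path)
  manifest$run_log <- log_path
  params <- list(
    seed = config$seed, x0 = config$x0, completeness = config$completeness,
    pm_ratio = config$pm_ratio, min_pm25_obs = config$min_pm25_obs,
    crs = config$crs,
    presets = list(short = config$preset_short,
                   long_all = config$preset_long_all,
                   long_cvd = config$preset_long_cvd),
    scenarios = lapply(config$scenarios, function(s)
      list(mode = s$mode, amount = s$amount)),
    limits = vapply(config$limits, `[[`, character(1), "name"),
    synthetic = !is.null(config$synthetic))
  mpath <- file.path(out, "manifest.json")
  writeLines(jsonlite::toJSON(list(files = manifest, parameters = params),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             mpath)
  manifest$manifest <- mpath
  invisible(manifest)
}

# county-level annual mean PM2.5-equivalent exposure from generated daily
# data: per county, the mean over its stations of the pooled PM2.5 mean
# (measured directly, or pm_ratio * PM10 otherwise); counties without a
# station fall back to the regional mean
synthetic_exposures <- function(daily, stations, region, pm_ratio) {
  pooled <- pm_summary(daily, limits = list(), by_year = FALSE)
  x25 <- vapply(stations$station_id, function(sid) {
    p25 <- pooled[pooled$station_id == sid & pooled$pollutant == "PM25", ]
    if (nrow(p25) == 1L) return(p25$mean)
    p10 <- pooled[pooled$station_id == sid & pooled$pollutant == "PM10", ]
    estimate_pm25_from_pm10(p10$mean, pm_ratio)
  }, numeric(1))
  reg_mean <- regional_mean(x25)
  exposure <- vapply(region_names(region), function(cn) {
    v <- x25[stations$county == cn]
    if (length(v)) mean(v) else reg_mean
  }, numeric(1))
  data.frame(area = region_names(region), exposure = exposure,
             stringsAsFactors = FALSE)
}

# shared allocation core: distribute any area-level count column across
# station cells by Thiessen weight
allocate_counts <- function(weights, tbl, value_col) {
  deaths_like <- tbl
  names(deaths_like)[names(deaths_like) == value_col] <- "deaths"
  out <- allocate_deaths(weights, deaths_like)
  names(out)[names(out) == "deaths"] <- value_col
  out
}

#' One-command synthetic demonstration run
#'
#' Generates the default synthetic data set and runs the full pipeline
#' into `out_dir`. Deterministic for a given seed.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (default 1).
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return Invisibly, the manifest of output files.
#' @export
run_demo <- function(out_dir, seed = 1L, quiet = TRUE) {
  cfg <- run_config(out_dir = out_dir,
                    synthetic = synthetic_config(seed = seed),
                    seed = seed)
  run_full(cfg, quiet = quiet)
}
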