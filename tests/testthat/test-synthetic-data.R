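test_that("station generation places the requested stations inside the region", {
  region <- synthetic_region(6)
  cfg <- synthetic_config(n_stations = 22, seed = 11)
  st <- generate_stations(cfg, region)
  expect_equal(nrow(st), 22)
  expect_false(anyDuplicated(st$station_id) > 0)
  inside <- mapply(function(cn, x, y) {
    any(vapply(region_names(region), function(nm)
      any(pmhia:::region_contains(region, nm, x, y)), logical(1)))
  }, st$county, st$lon, st$lat)
  expect_true(all(inside))
  # each station's recorded county actually contains it
  own <- mapply(function(cn, x, y) pmhia:::region_contains(region, cn, x, y),
                st$county, st$lon, st$lat)
  expect_true(all(own))
  expect_gte(sum(st$measures_pm25), 1)

  single <- generate_stations(synthetic_config(n_stations = 1, seed = 3),
                              unit_square_region())
  expect_equal(nrow(single), 1)
})

test_that("generation is bit-identical under a fixed seed", {
  region <- synthetic_region(4)
  cfg <- small_cfg()
  expect_identical(generate_stations(cfg, region), generate_stations(cfg, region))
  st <- generate_stations(cfg, region)
  expect_identical(generate_daily_pm(cfg, st), generate_daily_pm(cfg, st))
  areas <- data.frame(area = region_names(region), exposure = c(12, 18, 25, 9))
  expect_identical(generate_population_and_deaths(cfg, areas),
                   generate_population_and_deaths(cfg, areas))
})

test_that("a degenerate region polygon is rejected", {
  expect_error(region_polygons(list(bad = cbind(c(0, 1, 2), c(0, 0, 0)))),
               "zero-area|degenerate")
})

test_that("noise-free aseasonal complete series is constant at the drawn annual mean", {
  cfg <- synthetic_config(n_stations = 2, n_years = 1, seasonal_amplitude = 0,
                          noise_sd = 0, missing_fraction = 0, seed = 5)
  st <- generate_stations(cfg, unit_square_region())
  daily <- generate_daily_pm(cfg, st)
  for (sid in st$station_id) {
    v <- daily$value[daily$station_id == sid & daily$pollutant == "PM10"]
    expect_equal(length(v), 366)  # 2012 is a leap year; leap days are kept
    expect_equal(length(unique(v)), 1L)
    expect_true(v[1] >= cfg$pm10_annual_mean_range[1] &&
                  v[1] <= cfg$pm10_annual_mean_range[2])
  }
})

test_that("generated series have winter maxima, the target PM2.5/PM10 ratio, and the configured gaps", {
  cfg <- synthetic_config(n_stations = 6, n_years = 3, seed = 21,
                          seasonal_amplitude = 8, noise_sd = 3,
                          missing_fraction = 0.1, pm25_station_fraction = 0.5)
  st <- generate_stations(cfg, synthetic_region(4))
  daily <- generate_daily_pm(cfg, st)
  expect_true(all(daily$value >= 0))
  mo <- as.integer(format(daily$date, "%m"))
  for (sid in st$station_id) {
    v10 <- daily[daily$station_id == sid & daily$pollutant == "PM10", ]
    m <- mo[daily$station_id == sid & daily$pollutant == "PM10"]
    # amplitude (8) > 2 * noise_sd (3): DJF above JJA for every station
    expect_gt(mean(v10$value[m %in% c(12, 1, 2)]),
              mean(v10$value[m %in% c(6, 7, 8)]))
    # empirical missing fraction at the configured value
    nd <- 365 + 365 + 366   # 2012-2014
    expect_lt(abs(1 - nrow(v10) / nd - cfg$missing_fraction), 0.02)
  }
  for (sid in st$station_id[st$measures_pm25]) {
    d <- daily[daily$station_id == sid, ]
    ratio <- mean(d$value[d$pollutant == "PM25"]) /
      mean(d$value[d$pollutant == "PM10"])
    expect_lt(abs(ratio - cfg$pm_ratio), 0.05)
  }
})

test_that("death counts are non-negative integers with the planted structure", {
  cfg <- small_cfg()
  areas <- data.frame(area = c("a", "b"), exposure = c(10, 30))
  pd <- generate_population_and_deaths(cfg, areas)
  expect_true(all(pd$population$persons >= 0))
  expect_true(all(pd$deaths$deaths >= 0))
  expect_true(all(pd$deaths$deaths == round(pd$deaths$deaths)))
  # cvd never exceeds all-cause within a stratum
  w <- merge(pd$deaths[pd$deaths$cause == "cvd", ],
             pd$deaths[pd$deaths$cause == "all_nonexternal", ],
             by = c("area", "year", "age_start"))
  expect_true(all(w$deaths.x <= w$deaths.y))
  expect_error(generate_population_and_deaths(cfg,
                 data.frame(area = "a", exposure = NA_real_)),
               "missing exposure")
})

test_that("with true_beta = 0 expected deaths are independent of exposure", {
  cfg <- synthetic_config(n_stations = 2, n_years = 50, true_beta = 0, seed = 9)
  areas <- data.frame(area = c("lo", "hi"), exposure = c(5, 50))
  pd <- generate_population_and_deaths(cfg, areas)
  tot <- tapply(pd$deaths$deaths[pd$deaths$cause == "all_nonexternal"],
                pd$deaths$area[pd$deaths$cause == "all_nonexternal"], sum)
  # equal Poisson means: totals agree within 4 relative sd
  expect_lt(abs(tot[["hi"]] / tot[["lo"]] - 1), 4 / sqrt(min(tot)))
})

test_that("the cardiovascular share of generated deaths matches the configured fraction", {
  cfg <- synthetic_config(n_stations = 2, n_years = 10, seed = 13)
  pd <- generate_population_and_deaths(cfg,
          data.frame(area = c("a", "b"), exposure = c(15, 20)))
  d <- pd$deaths
  share <- sum(d$deaths[d$cause == "cvd"]) /
    sum(d$deaths[d$cause == "all_nonexternal"])
  expect_lt(abs(share - 0.53), 0.01)
})
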