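test_that("summary statistics and exceedance accounting are correct on a known series", {
  # 10 days: two strictly over 50, one exactly at 50 (counts as compliant)
  v <- c(10, 20, 30, 40, 50, 55, 60, 5, 15, 25)
  s <- make_series("S1", "PM10", as.Date("2015-01-01") + 0:9, v)
  out <- pm_summary(s, limits = default_limit_sets()["RO_EU"])
  expect_equal(out$n_obs, 10)
  expect_equal(out$min, 5)
  expect_equal(out$max, 60)
  expect_equal(out$mean, mean(v))
  expect_equal(out$sd, sd(v))                      # sample sd, n - 1
  expect_equal(out$p5, unname(quantile(v, 0.05)))  # linear interpolation
  expect_equal(out$p95, unname(quantile(v, 0.95)))
  expect_equal(out$days_over_RO_EU, 2L)
  expect_equal(out$frac_over_RO_EU, 0.2)
  expect_false(out$annual_over_RO_EU)              # mean 31 <= 40

  const <- make_series("S2", "PM10", as.Date("2015-01-01") + 0:9, rep(10, 10))
  out <- pm_summary(const, limits = default_limit_sets()["RO_EU"])
  expect_equal(out$days_over_RO_EU, 0L)
  expect_equal(out$mean, 10)
  expect_equal(out$sd, 0)
  expect_error(pm_summary(s[0, ]), "empty")
})

test_that("percentiles bracket the data and exceedances shrink as the limit rises", {
  set.seed(30)
  v <- rgamma(500, shape = 2, scale = 12)
  s <- make_series("S1", "PM10", as.Date("2014-01-01") + 0:499, v)
  sets <- list(a = limit_set("a", pm10_daily = 20),
               b = limit_set("b", pm10_daily = 45),
               c = limit_set("c", pm10_daily = 50),
               d = limit_set("d", pm10_daily = 80))
  out <- pm_summary(s, limits = sets)
  expect_true(out$min <= out$p5 && out$p5 <= out$p95 && out$p95 <= out$max)
  expect_true(out$min <= out$mean && out$mean <= out$max)
  days <- unlist(out[paste0("days_over_", names(sets))])
  expect_true(all(diff(days) <= 0))
  expect_true(all(unlist(out[paste0("frac_over_", names(sets))]) <= 1))
})

test_that("pooled n_obs adds over disjoint years and low-capture years are flagged", {
  y1 <- make_series("S1", "PM10", as.Date("2015-01-01") + 0:364, rep(20, 365))
  y2 <- make_series("S1", "PM10", as.Date("2016-03-01") + 0:99, rep(30, 100))
  both <- pm_daily(rbind(y1, y2))
  pooled <- pm_summary(both)
  expect_equal(pooled$n_obs, 365 + 100)
  annual <- pm_summary(both, by_year = TRUE, completeness = 0.75)
  expect_equal(annual$complete[annual$year == 2015], TRUE)
  expect_equal(annual$complete[annual$year == 2016], FALSE)
})

test_that("monthly climatology reports absent months as NA, never zero", {
  d <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  keep <- format(d, "%m") != "02"
  s <- make_series("S1", "PM10", d[keep], rep(15, sum(keep)))
  clim <- monthly_climatology(s)
  expect_equal(nrow(clim), 12)
  expect_true(is.na(clim$mean[clim$month == 2]))
  expect_equal(clim$n_obs[clim$month == 2], 0L)
  expect_true(all(clim$mean[clim$month != 2] == 15))
})

test_that("winter-peaked synthetic series show a January-over-July climatology", {
  cfg <- synthetic_config(n_stations = 2, n_years = 2, seed = 17,
                          seasonal_amplitude = 8, noise_sd = 2)
  st <- generate_stations(cfg, unit_square_region())
  clim <- monthly_climatology(generate_daily_pm(cfg, st))
  jan <- clim$mean[clim$month == 1]
  jul <- clim$mean[clim$month == 7]
  expect_true(all(jan > jul))
})

test_that("the PM2.5~PM10 regression agrees with the normal-equation oracle", {
  set.seed(41)
  d <- as.Date("2015-01-01") + 0:19
  x <- runif(20, 5, 60)
  y <- 2 + 0.65 * x + rnorm(20, 0, 3)
  daily <- pm_daily(rbind(make_series("S1", "PM10", d, x),
                          make_series("S1", "PM25", d, y)))
  fit <- regress_pm25_on_pm10(daily, "S1")
  ora <- ols_oracle(x, y)
  expect_equal(fit$slope, ora$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, ora$intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, ora$r_squared, tolerance = 1e-9)
  expect_equal(fit$r^2, fit$r_squared, tolerance = 1e-12)
  expect_true(fit$f_significance >= 0 && fit$f_significance <= 1)

  # exact line: slope recovered exactly, perfect fit
  daily <- pm_daily(rbind(make_series("S1", "PM10", d, x),
                          make_series("S1", "PM25", d, 0.7 * x)))
  fit <- regress_pm25_on_pm10(daily, "S1")
  expect_equal(fit$slope, 0.7, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$f_significance, 1e-12)
  expect_equal(fit$mean_ratio, 0.7, tolerance = 1e-12)
})

test_that("regression input requirements are enforced", {
  d <- as.Date("2015-01-01") + 0:1
  daily <- pm_daily(rbind(make_series("S1", "PM10", d, c(1, 2)),
                          make_series("S1", "PM25", d, c(1, 2))))
  expect_error(regress_pm25_on_pm10(daily, "S1"), "fewer than 3")
  d <- as.Date("2015-01-01") + 0:9
  daily <- pm_daily(rbind(make_series("S1", "PM10", d, rep(10, 10)),
                          make_series("S1", "PM25", d, runif(10))))
  expect_error(regress_pm25_on_pm10(daily, "S1"), "zero variance")
})

test_that("F significance is uniform under independence", {
  set.seed(90)
  pvals <- replicate(200, {
    n <- 100
    d <- as.Date("2015-01-01") + seq_len(n) - 1
    daily <- pm_daily(rbind(
      make_series("S1", "PM10", d, pmax(0, rnorm(n, 20, 5))),
      make_series("S1", "PM25", d, pmax(0, rnorm(n, 14, 4)))))
    regress_pm25_on_pm10(daily, "S1")$f_significance
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("PM2.5 estimation from PM10 is a plain conversion with validation", {
  expect_equal(estimate_pm25_from_pm10(20), 14)
  expect_equal(estimate_pm25_from_pm10(0), 0)
  expect_equal(estimate_pm25_from_pm10(21.57), 15.099)
  expect_error(estimate_pm25_from_pm10(-1), "non-negative")
})

test_that("the regional mean is an unweighted permutation-invariant mean", {
  v <- c(13.85, 17.36, 21.22, 15.68, 19.30)
  expect_equal(regional_mean(v), 17.482)
  expect_equal(regional_mean(rev(v)), regional_mean(v))
  expect_equal(regional_mean(5.5), 5.5)
  expect_error(regional_mean(numeric(0)), "no station means")
})
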