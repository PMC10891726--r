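ages <- c(30, 40, 50, 60, 70, 80)
widths <- c(10, 10, 10, 10, 10, NA)

test_that("the abridged life table matches the independent oracle", {
  # constant hazard across groups
  P <- rep(50000, 6)
  D <- P * 0.01
  lt <- build_life_table(ages, widths, P, D)
  ora <- lt_oracle(ages, widths, P, D)
  for (col in c("q", "l", "d", "L", "T", "e")) {
    expect_equal(lt[[col]], ora[[col]], tolerance = 1e-9)
  }
  # a realistic rising schedule
  P <- c(96000, 86000, 72000, 50000, 26000, 10000)
  D <- c(190, 340, 720, 1100, 1300, 1300)
  lt <- build_life_table(ages, widths, P, D)
  ora <- lt_oracle(ages, widths, P, D)
  for (col in c("q", "l", "d", "L", "T", "e")) {
    expect_equal(lt[[col]], ora[[col]], tolerance = 1e-9)
  }
})

test_that("life-table structural invariants hold", {
  P <- c(96000, 86000, 72000, 50000, 26000, 10000)
  D <- c(190, 340, 720, 1100, 1300, 1300)
  lt <- build_life_table(ages, widths, P, D)
  expect_true(all(diff(lt$l) <= 0))
  expect_equal(lt$l[1], 1e5)
  expect_true(all(lt$q >= 0 & lt$q <= 1))
  expect_equal(lt$q[6], 1)
  expect_equal(sum(lt$d), 1e5, tolerance = 1e-9)
  expect_true(all(lt$e >= 0))

  # vanishing rates in closed groups leave the cohort intact to the open group
  lt0 <- build_life_table(ages, widths, P, c(rep(1e-9, 5), 1300))
  expect_equal(lt0$l[6], 1e5, tolerance = 1e-3)

  # doubling population with deaths fixed halves every central rate
  lt2 <- build_life_table(ages, widths, 2 * P, D)
  expect_equal(lt2$M, lt$M / 2, tolerance = 1e-12)

  expect_error(build_life_table(ages, widths, P, c(D[-6], 0)), "open-ended")
  expect_error(build_life_table(ages, widths, c(P[-6], 0), D), "positive")
})

test_that("life expectancy is robust to the grouping width on a smooth schedule", {
  # Gompertz hazard, five-year versus ten-year grouping of the same rates
  gomp <- function(x) 0.000156 * exp(0.085 * x)
  a10 <- ages; w10 <- widths
  a5 <- seq(30, 80, by = 5); w5 <- c(rep(5, 10), NA)
  mid <- function(a, w) ifelse(is.na(w), a + 5, a + w / 2)
  P10 <- rep(1e5, 6); P5 <- rep(1e5, 11)
  e10 <- build_life_table(a10, w10, P10, P10 * gomp(mid(a10, w10)))$e[1]
  e5 <- build_life_table(a5, w5, P5, P5 * gomp(mid(a5, w5)))$e[1]
  expect_lt(abs(e10 - e5), 0.5)
})

test_that("impacted deaths scale by a single age-independent exponential factor", {
  D <- c(190, 340, 720, 1100, 1300, 1300)
  expect_equal(impacted_deaths(D, 0.005826, 0), D)
  out <- impacted_deaths(D, 0.005826, 5)
  expect_equal(out / D, rep(exp(-0.02913), 6), tolerance = 1e-12)
  expect_equal(impacted_deaths(100, 0.005826, 5), 97.1290188534338,
               tolerance = 1e-9)
  expect_error(impacted_deaths(D, -0.001, 5), "non-negative")
  expect_error(impacted_deaths(D, 0.005, -1), "non-negative")
})

test_that("scenarios translate to concentration decreases with clamping", {
  expect_equal(delta_x_for(scenario("decrease_by", 5), 17.36), 5)
  expect_equal(delta_x_for(scenario("decrease_to", 10), 17.36), 7.36)
  expect_equal(delta_x_for(scenario("decrease_to", 10), 8), 0)
  expect_error(scenario("decrease_by", -2))
})

test_that("the HIA equals its closed-form deaths-avoided identity and responds monotonically", {
  P <- c(96000, 86000, 72000, 50000, 26000, 10000)
  D <- c(190, 340, 720, 1100, 1300, 1300)
  p <- risk_params_preset("pm25_long_all")
  h <- run_hia(ages, widths, P, D, x_current = 17.36, params = p,
               scn = scenario("decrease_by", 5), unit = "u")
  expect_equal(h$deaths_avoided, sum(D) * (1 - exp(-p$beta * 5)),
               tolerance = 1e-9)
  expect_equal(h$deaths_avoided_per_100k,
               h$deaths_avoided / sum(P) * 1e5, tolerance = 1e-9)
  expect_gt(h$le_gain_months, 0)
  expect_true(h$deaths_avoided_low <= h$deaths_avoided &&
                h$deaths_avoided <= h$deaths_avoided_high)

  # delta_x = 0 and beta = 0 are exact null effects
  h0 <- run_hia(ages, widths, P, D, 8, p, scenario("decrease_to", 10))
  expect_equal(h0$deaths_avoided, 0)
  expect_equal(h0$le_gain_months, 0)
  pb0 <- risk_params(0, baseline = 10, horizon = "long")
  hb0 <- run_hia(ages, widths, P, D, 20, pb0, scenario("decrease_by", 5))
  expect_equal(hb0$deaths_avoided, 0)
  expect_equal(hb0$le_gain_months, 0)

  # life-expectancy gain non-decreasing in delta_x and in beta
  gains_dx <- vapply(c(1, 3, 5, 8), function(dx) {
    run_hia(ages, widths, P, D, 20, p, scenario("decrease_by", dx))$le_gain_months
  }, numeric(1))
  expect_true(all(diff(gains_dx) > 0))
  gains_b <- vapply(c(0.002, 0.005826, 0.011), function(b) {
    run_hia(ages, widths, P, D, 20, risk_params(b, baseline = 10, horizon = "long"),
            scenario("decrease_by", 5))$le_gain_months
  }, numeric(1))
  expect_true(all(diff(gains_b) > 0))

  # baseline table equals impacted table field-by-field when delta_x = 0
  lt_a <- build_life_table(ages, widths, P, D)
  lt_b <- build_life_table(ages, widths, P, impacted_deaths(D, p$beta, 0))
  expect_equal(lt_a, lt_b, tolerance = 1e-15)
})

test_that("a population-scale fixture reproduces its analytically constructed deaths-avoided target", {
  # fixture constructed by inverting sum(D) * (1 - exp(-beta * 5)) = 172.4:
  # age distribution of deaths fixed, total scaled to hit the target
  p <- risk_params_preset("pm25_long_all")
  target <- 172.4
  D_total <- target / (1 - exp(-p$beta * 5))
  shape <- c(190, 340, 720, 1100, 1300, 1300)
  D <- shape / sum(shape) * D_total
  P <- c(96000, 86000, 72000, 50000, 26000, 10000)  # ~340k aged 30+
  h <- run_hia(ages, widths, P, D, x_current = 17.36, params = p,
               scn = scenario("decrease_by", 5), unit = "county-scale")
  expect_lt(abs(h$deaths_avoided - target) / target, 0.01)
  expect_equal(h$deaths_avoided_per_100k, target / sum(P) * 1e5,
               tolerance = 1e-6)
  # months of life expectancy gained at 30: same order as published regional
  # impacted-life-table assessments (a few months)
  expect_gt(h$le_gain_months, 0.5)
  expect_lt(h$le_gain_months, 12)
})
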