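#' Abridged life table from population and death counts
#'
#' Builds a standard abridged (grouped-age) period life table. Central
#' death rates M = D/P are converted to interval death probabilities with
#' the mid-interval assumption (average fraction of the interval lived by
#' those dying, `a = 0.5` by default): q = m*M / (1 + m*(1-a)*M) for a
#' closed group of width m. The terminal open-ended group has q = 1 and
#' person-years L = l/M, which requires deaths there. Survivors l start at
#' the radix, table deaths d = l*q, closed-group person-years
#' L = m*(l - (1-a)*d), T is the cumulative person-years above each age and
#' life expectancy e = T/l.
#'
#' A closed-group probability that would exceed 1 (only possible at extreme
#' rates, m*M > 2) is capped at 1 with a warning.
#'
#' @param age_start Integer vector of group starting ages, ascending.
#' @param width Group widths in years; `NA` for the single open-ended
#'   terminal group.
#' @param population Persons alive in each group (> 0).
#' @param deaths Annual deaths in each group (>= 0; > 0 in the open group).
#'   Fractional deaths are allowed (e.g. impacted or allocated counts).
#' @param radix Starting cohort size (default 100000).
#' @param a Average fraction of the interval lived by those dying in it
#'   (default 0.5).
#' @return data.frame of class `life_table` with columns age_start, width,
#'   population, deaths, M, q, l, d, L, T, e.
#' @export
build_life_table <- function(age_start, width, population, deaths,
                             radix = 1e5, a = 0.5) {
  n <- length(age_start)
  stopifnot(n >= 1L, length(width) == n, length(population) == n,
            length(deaths) == n, radix > 0, a >= 0, a <= 1)
  o <- order(age_start)
  age_start <- age_start[o]; width <- width[o]
  population <- population[o]; deaths <- deaths[o]
  check_age_groups(age_start, width, "life table")
  if (any(population <= 0)) stop("population must be positive in every age group")
  if (any(deaths < 0)) stop("deaths must be non-negative")
  if (deaths[n] <= 0) {
    stop("open-ended age group has no deaths; its person-years are undefined")
  }
  M <- deaths / population
  q <- numeric(n)
  closed <- seq_len(n - 1L)
  if (n > 1L) {
    m <- width[closed]
    q[closed] <- m * M[closed] / (1 + m * (1 - a) * M[closed])
    if (any(q[closed] > 1)) {
      warning("death probability capped at 1 in ", sum(q[closed] > 1), " group(s)")
      q[closed] <- pmin(q[closed], 1)
    }
  }
  q[n] <- 1
  l <- numeric(n)
  l[1] <- radix
  for (i in seq_len(n - 1L)) l[i + 1L] <- l[i] * (1 - q[i])
  d <- l * q
  L <- numeric(n)
  if (n > 1L) L[closed] <- width[closed] * (l[closed] - (1 - a) * d[closed])
  L[n] <- if (M[n] > 0) l[n] / M[n] else 0
  Tt <- rev(cumsum(rev(L)))
  e <- Tt / l
  out <- data.frame(age_start = age_start, width = width,
                    population = population, deaths = deaths,
                    M = M, q = q, l = l, d = d, L = L, T = Tt, e = e)
  attr(out, "radix") <- radix
  attr(out, "a") <- a
  class(out) <- c("life_table", "data.frame")
  out
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %d age groups, radix %g; e(%d) = %.2f years\n",
              nrow(x), attr(x, "radix"), x$age_start[1], x$e[1]))
  print.data.frame(cbind(x[1:4], round(x[5:11], 5)), row.names = FALSE)
  invisible(x)
}

#' Deaths under a reduced-exposure counterfactual
#'
#' Scales each age group's observed deaths by exp(-beta * delta_x), the
#' log-linear survival benefit of reducing the annual mean by delta_x
#' ug/m3. The factor is common to all age groups; fractional deaths are
#' retained.
#'
#' @param deaths Numeric vector of deaths per age group, >= 0.
#' @param beta Concentration-response coefficient, per ug/m3, >= 0.
#' @param delta_x Concentration decrease, ug/m3, >= 0.
#' @return Impacted deaths, same length as `deaths`.
#' @export
impacted_deaths <- function(deaths, beta, delta_x) {
  stopifnot(all(deaths >= 0), length(beta) == 1L, length(delta_x) == 1L)
  if (beta < 0) stop("beta must be non-negative")
  if (delta_x < 0) stop("delta_x must be non-negative")
  deaths * exp(-beta * delta_x)
}

#' Exposure-reduction scenario
#'
#' Either an absolute decrease of the annual mean (`decrease_by`) or a
#' decrease to a stated level (`decrease_to`, clamped at zero when the
#' current mean is already below it).
#'
#' @param mode `"decrease_by"` or `"decrease_to"`.
#' @param amount Decrease (or target level), ug/m3, >= 0.
#' @param pollutant Pollutant the scenario applies to (default `"PM25"`).
#' @return Object of class `scenario`.
#' @export
scenario <- function(mode = c("decrease_by", "decrease_to"), amount,
                     pollutant = "PM25") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(amount), length(amount) == 1L, amount >= 0)
  structure(list(mode = mode, amount = amount, pollutant = pollutant),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s %g ug/m3 (%s)\n",
              sub("_", " ", x$mode), x$amount, x$pollutant))
  invisible(x)
}

#' Concentration decrease implied by a scenario
#'
#' @param scn A [scenario()] object.
#' @param x_current Current annual mean, ug/m3, >= 0.
#' @return delta_x, ug/m3 (never negative).
#' @export
delta_x_for <- function(scn, x_current) {
  stopifnot(inherits(scn, "scenario"), x_current >= 0)
  switch(scn$mode,
         decrease_by = scn$amount,
         decrease_to = max(0, x_current - scn$amount))
}

#' Long-term health impact assessment under an exposure scenario
#'
#' Runs the impacted-life-table method for one population unit: build the
#' baseline abridged life table, scale observed deaths by exp(-beta *
#' delta_x), rebuild, and report (i) annual deaths avoided, computed on the
#' observed death counts (a population-scale annual figure, not a radix
#' quantity), (ii) deaths avoided per 100,000 persons at risk, and (iii)
#' the gain in life expectancy at the table's starting age, in months.
#' Where the parameters carry beta bounds the whole assessment is rerun at
#' each bound (no delta-method approximation).
#'
#' @param age_start,width,population,deaths Age-group structure as in
#'   [build_life_table()]; deaths are annual counts for the endpoint of
#'   interest.
#' @param x_current Current annual mean concentration, ug/m3.
#' @param params A [risk_params()] object (long-term horizon expected).
#' @param scn A [scenario()] object.
#' @param pop_at_risk Denominator for the per-100,000 rate (default: the
#'   summed input population, i.e. persons aged 30+ when the table starts
#'   at 30).
#' @param unit Label for the population unit (station or county).
#' @return Object of class `hia_result`: a one-row data.frame with columns
#'   unit, endpoint, scenario, delta_x, deaths_avoided (_low/_high),
#'   deaths_avoided_per_100k (_low/_high), le_gain_months (_low/_high).
#' @export
run_hia <- function(age_start, width, population, deaths, x_current,
                    params, scn, pop_at_risk = sum(population),
                    unit = NA_character_) {
  stopifnot(inherits(params, "risk_params"), inherits(scn, "scenario"))
  if (pop_at_risk <= 0) stop("pop_at_risk must be positive")
  dx <- delta_x_for(scn, x_current)
  one <- function(beta) {
    if (is.na(beta)) return(c(NA_real_, NA_real_, NA_real_))
    base <- build_life_table(age_start, width, population, deaths)
    imp <- build_life_table(age_start, width, population,
                            impacted_deaths(deaths, beta, dx))
    avoided <- sum(deaths) - sum(impacted_deaths(deaths, beta, dx))
    c(avoided, avoided / pop_at_risk * 1e5, 12 * (imp$e[1] - base$e[1]))
  }
  ctr <- one(params$beta)
  lo <- one(params$beta_low)
  hi <- one(params$beta_high)
  out <- data.frame(
    unit = unit, endpoint = params$endpoint,
    scenario = sprintf("%s_%g", scn$mode, scn$amount),
    x_current = x_current, delta_x = dx,
    deaths_avoided_low = lo[1], deaths_avoided = ctr[1], deaths_avoided_high = hi[1],
    deaths_avoided_per_100k_low = lo[2], deaths_avoided_per_100k = ctr[2],
    deaths_avoided_per_100k_high = hi[2],
    le_gain_months_low = lo[3], le_gain_months = ctr[3], le_gain_months_high = hi[3],
    stringsAsFactors = FALSE)
  class(out) <- c("hia_result", "data.frame")
  out
}

#' @export
print.hia_result <- function(x, ...) {
  cat(sprintf("<hia_result> %s, %s, scenario %s (delta_x = %.2f ug/m3)\n",
              x$unit, x$endpoint, x$scenario, x$delta_x))
  cat(sprintf("  deaths avoided/yr: %.1f [%.1f, %.1f]  per 100k: %.1f  LE gain: %.2f months\n",
              x$deaths_avoided, x$deaths_avoided_low, x$deaths_avoided_high,
              x$deaths_avoided_per_100k, x$le_gain_months))
  invisible(x)
}
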