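#' Concentration-response parameters
#'
#' Bundles the log-linear concentration-response coefficient (central value
#' with optional low/high bounds, per ug/m3) and the baseline concentration
#' X0 below which no excess risk is attributed. The relative risk at annual
#' mean x is RR = exp(beta * (x - X0)).
#'
#' @param beta Central concentration-response coefficient, per ug/m3.
#' @param beta_low,beta_high Lower/upper bounds of beta (optional, `NA` to
#'   omit); must bracket `beta`.
#' @param baseline Baseline concentration X0, ug/m3, >= 0 (default 10).
#' @param pollutant `"PM10"` or `"PM25"`.
#' @param endpoint `"all_nonexternal"` or `"cvd"`.
#' @param horizon `"short"` or `"long"` term exposure.
#' @return Object of class `risk_params`.
#' @export
risk_params <- function(beta, beta_low = NA_real_, beta_high = NA_real_,
                        baseline = 10, pollutant = "PM25",
                        endpoint = c("all_nonexternal", "cvd"),
                        horizon = c("short", "long")) {
  endpoint <- match.arg(endpoint)
  horizon <- match.arg(horizon)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  stopifnot(baseline >= 0, pollutant %in% POLLUTANTS)
  if (!is.na(beta_low) && beta_low > beta) stop("beta_low must be <= beta")
  if (!is.na(beta_high) && beta_high < beta) stop("beta_high must be >= beta")
  structure(list(beta = beta, beta_low = beta_low, beta_high = beta_high,
                 baseline = baseline, pollutant = pollutant,
                 endpoint = endpoint, horizon = horizon),
            class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf("<risk_params %s %s-term %s> beta = %g [%g, %g] per ug/m3, X0 = %g ug/m3\n",
              x$pollutant, x$horizon, x$endpoint, x$beta, x$beta_low,
              x$beta_high, x$baseline))
  invisible(x)
}

#' Registered concentration-response coefficient presets
#'
#' Literature coefficients kept as data: the WHO/Anderson short-term PM10
#' all-cause slope 0.00059 (+/- 0.00019), the Ostro alternative 0.0008, the
#' short-term PM2.5 slope 0.000598 (0.000299-0.000895), and the long-term
#' PM2.5 slopes for total non-external mortality (0.005826, the log of
#' Pope's RR 1.06 per 10 ug/m3; bounds from the 1.02-1.11 interval) and for
#' cardiovascular mortality (0.011, from RR 1.12, bounds 1.08-1.15).
#'
#' @return data.frame with columns preset, pollutant, horizon, endpoint,
#'   beta, beta_low, beta_high.
#' @export
risk_presets <- function() {
  data.frame(
    preset = c("pm10_short_all", "pm10_short_all_ostro", "pm25_short_all",
               "pm25_long_all", "pm25_long_cvd"),
    pollutant = c("PM10", "PM10", "PM25", "PM25", "PM25"),
    horizon = c("short", "short", "short", "long", "long"),
    endpoint = c("all_nonexternal", "all_nonexternal", "all_nonexternal",
                 "all_nonexternal", "cvd"),
    beta = c(0.00059, 0.0008, 0.000598, 0.005826, 0.011),
    beta_low = c(0.0004, NA, 0.000299, log(1.02) / 10, log(1.08) / 10),
    beta_high = c(0.00078, NA, 0.000895, log(1.11) / 10, log(1.15) / 10),
    stringsAsFactors = FALSE)
}

#' Build risk parameters from a named preset
#'
#' @param preset One of the names in [risk_presets()].
#' @param baseline Baseline concentration X0, ug/m3 (default 10).
#' @return A [risk_params()] object.
#' @export
risk_params_preset <- function(preset, baseline = 10) {
  p <- risk_presets()
  i <- match(preset, p$preset)
  if (is.na(i)) stop("unknown preset '", preset, "'; see risk_presets()")
  risk_params(beta = p$beta[i], beta_low = p$beta_low[i],
              beta_high = p$beta_high[i], baseline = baseline,
              pollutant = p$pollutant[i], endpoint = p$endpoint[i],
              horizon = p$horizon[i])
}

#' Relative risk at an annual mean concentration
#'
#' RR = exp(beta * (x - X0)) for the central coefficient and, where the
#' parameters carry them, the low/high bounds. Exposure below the baseline
#' gives RR < 1 and is flagged, not clamped.
#'
#' @param x Annual mean concentration, ug/m3, >= 0 (vectorised).
#' @param params A [risk_params()] object.
#' @return data.frame with columns x, rr_low, rr, rr_high, below_baseline.
#' @export
relative_risk <- function(x, params) {
  stopifnot(inherits(params, "risk_params"))
  if (any(x < 0)) stop("concentration must be non-negative")
  dx <- x - params$baseline
  data.frame(x = x,
             rr_low = if (is.na(params$beta_low)) NA_real_ else exp(params$beta_low * dx),
             rr = exp(params$beta * dx),
             rr_high = if (is.na(params$beta_high)) NA_real_ else exp(params$beta_high * dx),
             below_baseline = dx < 0)
}

#' Attributable fraction and deaths assigned to a pollutant
#'
#' AF = (RR - 1)/RR and N_assigned = AF * N_total. With RR below 1 (exposure
#' under the baseline) the attributable fraction is clipped at zero by
#' default; `allow_negative = TRUE` keeps the signed value for sensitivity
#' work. Assigned deaths are returned unrounded with a rounded presentation
#' column.
#'
#' @param rr Relative risk(s), > 0 (vectorised).
#' @param n_total Total deaths in the unit (scalar or same length as `rr`).
#' @param allow_negative Keep negative attributable fractions (default
#'   `FALSE`).
#' @return data.frame with columns rr, af, n_total, n_assigned,
#'   n_assigned_rounded.
#' @export
attributable_deaths <- function(rr, n_total, allow_negative = FALSE) {
  if (any(is.na(rr)) || any(rr <= 0)) stop("rr must be positive")
  if (any(n_total < 0)) stop("n_total must be non-negative")
  af <- (rr - 1) / rr
  if (!allow_negative) af <- pmax(af, 0)
  n <- af * n_total
  data.frame(rr = rr, af = af, n_total = n_total, n_assigned = n,
             n_assigned_rounded = round(n))
}

#' Summary statistics of station-level relative risks
#'
#' Mean, median, sample standard deviation, standard error, range, and the
#' 95 percent t-interval of the mean across stations; `NA` entries
#' (stations without the pollutant) are dropped before counting.
#'
#' @param rrs Numeric vector of central RRs, possibly with `NA` for
#'   stations lacking the pollutant.
#' @return Object of class `rr_summary` (a list) with fields mean, median,
#'   sd, se, min, max, count, ci_halfwidth, ci_lower, ci_upper.
#' @export
station_rr_summary <- function(rrs) {
  rrs <- rrs[!is.na(rrs)]
  n <- length(rrs)
  if (n < 2L) stop("at least two station RRs are required")
  s <- stats::sd(rrs)
  se <- s / sqrt(n)
  hw <- stats::qt(0.975, n - 1) * se
  structure(list(mean = mean(rrs), median = stats::median(rrs), sd = s,
                 se = se, min = min(rrs), max = max(rrs), count = n,
                 ci_halfwidth = hw, ci_lower = mean(rrs) - hw,
                 ci_upper = mean(rrs) + hw),
            class = "rr_summary")
}

#' @export
print.rr_summary <- function(x, ...) {
  cat(sprintf("<rr_summary> n = %d stations\n", x$count))
  cat(sprintf("  mean %.4f (95%% CI %.4f-%.4f), median %.4f, sd %.5f, se %.5f\n",
              x$mean, x$ci_lower, x$ci_upper, x$median, x$sd, x$se))
  cat(sprintf("  range %.5f-%.5f\n", x$min, x$max))
  invisible(x)
}
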