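---
title: "Methods: particulate-matter health impact assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particulate-matter health impact assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhia)
```

## The model

`pmhia` quantifies the mortality burden of airborne particulate matter with
the standard quantitative-HIA chain used by WHO-style assessments and the
Aphekom/AirQ+ family of tools.

**Concentration–response.** Risk is log-linear in the annual mean
concentration $X$ (µg/m³):

$$RR = e^{\beta (X - X_0)}$$

where $X_0$ is a baseline concentration below which no excess risk is
attributed and $\beta$ is the concentration–response coefficient per µg/m³.
The attributable fraction and the deaths assigned to the exposure are

$$AF = \frac{RR - 1}{RR}, \qquad N_{assigned} = AF \cdot N_{total}.$$

The model assumes no threshold other than $X_0$, no effect modification by
age or season within a unit, and that the annual mean is an adequate
exposure metric for the population of the unit (station territory or
county).

**Impacted life table.** For long-term effects, observed deaths
${}_nD_m$ in the age group starting at $n$ and covering $m$ years are scaled
under a counterfactual reduction $\Delta x$:

$$ {}_nD_m^{impacted} = {}_nD_m \cdot e^{-\beta \Delta x} $$

The factor is deliberately age-independent. A baseline and an impacted
abridged life table are built from the same populations, and the package
reports (i) annual deaths avoided, $\sum_n {}_nD_m (1 - e^{-\beta \Delta x})$,
computed on the *observed* death counts so the figure is an annual,
population-scale quantity rather than a property of the synthetic radix
cohort; (ii) the same per 100,000 persons at risk; and (iii) the gain in
life expectancy at the table's starting age (age 30 by default, the age at
which long-term PM₂.₅ burdens are conventionally quoted), in months. The
denominator for the per-100,000 rate is an explicit argument
(`pop_at_risk`), defaulting to the summed 30+ population of the unit,
because published per-capita figures are sensitive to exactly this choice
and it is often left implicit.

**Uncertainty.** Where a preset carries bounds, the *entire* assessment is
re-run at $\beta_{low}$ and $\beta_{high}$; no delta-method approximation is
used. For the long-term coefficients, which circulate in the literature as
relative risks per 10 µg/m³ with confidence intervals (1.06, CI 1.02–1.11
all-cause; 1.12, CI 1.08–1.15 cardiovascular), the bounds are
$\ln(RR_{CI})/10$.

## Tunable parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `beta` (presets) | per µg/m³ | see `risk_presets()` | WHO/Anderson, Ostro, Pope values; presets are data, not code |
| `baseline` ($X_0$) | µg/m³ | 10 | a conventional background level; fully configurable since published station tables are rarely explicit about it |
| scenario | µg/m³ | decrease by 5; decrease to 10 | the two policy-relevant counterfactuals: an incremental abatement and attainment of the former WHO annual guideline |
| age groups | years | 30–39 … 70–79, 80+ ($m = 10$) | mortality from long-term PM exposure is assessed for adults 30+; the group structure is configurable (5-year inputs are common) |
| completeness | fraction | 0.75 | a year with under 75 % data capture yields an unreliable annual mean; it is flagged, never silently dropped, and pooled multi-year statistics ignore the threshold by design |
| `pm_ratio` | – | 0.7 | regional PM₂.₅/PM₁₀ mean ratio; used to estimate PM₂.₅ where only PM₁₀ is measured, and as the generator's target ratio |
| `min_pm25_obs` | days | 365 | below one year of PM₂.₅ data a station's own mean is considered less reliable than the conversion |

## The abridged life table

Central rates $M = D/P$ are converted with the mid-interval assumption
($a = 0.5$, the average fraction of the interval lived by those dying in
it):

$$ q = \frac{m M}{1 + m (1 - a) M} $$

for a closed group of width $m$; the terminal open-ended group has $q = 1$
and person-years $L = l/M$ (hence it must contain deaths — a zero there is a
hard error, not a silent patch). Survivors start at a radix of 100,000,
$d = l q$, closed-group $L = m (l - (1-a) d)$, $T$ cumulates $L$ from the
oldest group, and $e = T/l$. A closed-group $q$ that would exceed 1 (only
possible at extreme rates, $mM > 2$) is capped with a warning. The guidance
this method family follows publishes no construction formulas, so the
standard demographic abridged method above is adopted and tested against an
independent scalar-recursion oracle to $10^{-9}$; on smooth (Gompertz)
schedules, 5-year and 10-year groupings of the same rates agree on $e(30)$
within half a year.

## Spatial allocation

Deaths are registered by county; exposure is measured at stations. The
package assigns each station a Thiessen (Voronoi) territory: the Voronoi
diagram of station points is built by half-plane intersection, bounded by a
padded envelope so outer cells are finite, and each cell is clipped against
each county polygon. The weight of station $s$ in county $c$ is
$\mathrm{area}(\mathrm{cell}_s \cap c) / \mathrm{area}(c)$; per county the
weights sum to one, and allocated deaths are conserved exactly (weights are
renormalised against float noise in the clipping, then checked to $10^{-9}$).
Cells deliberately cross county lines, so a county without its own station
is covered by neighbouring stations — the alternative (clipping each cell to
its own county) would leave such counties unallocated.

Area weights demand equal-area treatment, so lon/lat inputs are projected
with a sinusoidal projection about the region's central meridian before any
geometry is computed; planar inputs (e.g. the synthetic region, in km) are
used as-is. The geometry code is deliberately minimal — shoelace areas,
even-odd point-in-polygon, Sutherland–Hodgman clipping — because the problem
size is tens of points and a handful of polygons; it is validated against a
Monte-Carlo nearest-station oracle (10⁶ uniform points, agreement within
0.003 per station). Interior rings (holes) in county polygons are rejected
rather than mishandled.

## The synthetic-data generator

The generator emulates the data regime the pipeline is built for, with
every default chosen once as the realistic study condition:

* **22 stations, 10 years of daily data starting 2012**, station-level
  multi-annual PM₁₀ means drawn uniformly in 9–31 µg/m³ — the observed
  range of a mixed urban/suburban/industrial regional network.
* **Seasonality** as a single annual sinusoid peaking in mid-January
  (amplitude 8 µg/m³ by default). Real monthly profiles are not perfectly
  sinusoidal (and high-altitude background sites can even invert the
  pattern), but a single harmonic reproduces the feature the analysis
  consumes: winter means above summer means.
* **Gaps** uniform at random (10 % by default); real missingness is bursty
  (instrument outages), so completeness flags are exercised but gap
  *clustering* is not.
* **PM₂.₅** at ~25 % of stations, as `0.7 × PM₁₀` plus independent noise —
  matching both the sparse PM₂.₅ coverage of real networks and the observed
  regional ratio.
* **Populations** of 340,000 aged 30+ per area, split across the 10-year
  groups with geometrically declining shares; **deaths** Poisson with mean
  $P \cdot rate \cdot e^{\beta_{true}(X - X_0)}$, i.e. a *planted*
  concentration–response signal with configurable $\beta_{true}$ (default
  0.005826), and a binomial cardiovascular share of 0.53. The Poisson/
  binomial noise model is the generator's own choice; registry data come
  with no stated generative law.

What passing tests on these data do show: the estimators recover a known
$\beta$ from 50 areas within two standard errors, exceedance accounting and
life-table arithmetic are exact, and allocation conserves totals. What they
do not show: robustness to confounding, to bursty missingness, to
non-log-linear dose response, or to exposure measurement error — none of
which the generator emulates.

## Numerical choices and edge cases

* "Over the limit" is strictly greater; a day exactly at the limit is
  compliant.
* Percentiles use linear interpolation between order statistics (R type 7).
* Standard deviations are sample (n−1) throughout; the across-station RR
  summary uses the t-based 95 % interval of the mean.
* The OLS fit uses closed-form sums; its F significance is the upper tail
  of $F(1, n-2)$. Under 3 paired dates or zero PM₁₀ variance are errors.
* $RR < 1$ (exposure below baseline) is allowed and flagged; the
  attributable fraction is clipped at zero by default because assigning
  negative deaths is epidemiologically meaningless, with
  `allow_negative = TRUE` preserving the signed value for sensitivity work.
* Relative risks are rounded to 3 decimals and deaths to integers only in
  presentation columns; all internal arithmetic is unrounded, and allocated
  or impacted deaths stay fractional.
* All generator randomness derives from a single integer seed (sub-streams
  are offset per generator so each is reproducible in isolation); a
  pipeline rerun with the same seed is byte-identical in every tabular
  output.
* Ingest is strict: negative concentrations, unknown pollutant codes,
  duplicate observations and broken age-group partitions are errors naming
  the offending row or stratum — silent column drift is the main hazard of
  routine exports.

## Problem sizes

The test suite runs the full synthetic demonstration (22 stations × 10
years, ~92,000 daily observations) in a few seconds on one core; the
property suite uses 50 areas × 10 replicates for parameter recovery and 10⁶
Monte-Carlo points for the Voronoi oracle. These sizes were chosen as the
smallest that exercise every code path at statistically meaningful
precision.

## Known limitations

* No meteorological covariates, no trend analytics, no DALY computation,
  no kriging/IDW exposure surfaces — the pipeline implements Thiessen
  allocation and the log-linear model only.
* County polygons with interior rings are rejected.
* The cross-county Voronoi rule is a modelling choice (configurable data
  flow, fixed rule); where station territories and administrative units
  differ strongly, allocated totals inherit that assumption.
* Short-term and long-term coefficients are applied to the same annual-mean
  exposure metric; daily-series short-term designs (case-crossover, GAM
  time series) are out of scope.
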