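Package: pmhia
Title: Health Impact Assessment of Particulate Matter Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the public-health burden of airborne
    particulate matter (PM10 and PM2.5) from routine monitoring and vital
    statistics data. Provides descriptive statistics and exceedance
    accounting against regulatory and WHO air-quality limits, log-linear
    concentration-response relative risk and attributable mortality for
    short-term exposure, abridged life-table health impact assessment
    (deaths avoided and life-expectancy gain) under exposure-reduction
    scenarios for long-term exposure, Thiessen (Voronoi) polygon allocation
    of area-level deaths to monitoring stations, and a synthetic-data
    generator that emulates seasonal pollutant series, age-structured
    populations and mortality with a configurable planted
    concentration-response signal.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
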