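Package: heatburden
Title: Heatwave Detection, Distributed-Lag Mortality Models, and Attributable Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for quantifying the mortality burden of
    heatwaves from daily time series. Detects heatwaves as runs of days whose
    maximum temperature exceeds a location-specific percentile threshold,
    computes exposure indicators (cumulative excessive degree-days, person-days),
    fits location-level distributed-lag quasi-Poisson models of the
    heatwave-mortality association with a natural-cubic-spline lag structure,
    pools cumulative effects across locations by DerSimonian-Laird
    random-effects meta-analysis, and converts pooled effects into attributable
    numbers and fractions with Monte-Carlo confidence intervals. Includes a
    synthetic-data generator with known ground truth for parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
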