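Package: heatfootprint
Title: Welfare Footprint of Heat Stress in Pasture Beef Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the welfare burden of heat stress in pasture-raised
    beef cattle as cumulative time spent in thermal discomfort of graded
    intensity. Daily weather series (NASA-POWER-style or tidy CSV, or a
    seeded synthetic climate generator) are converted to the Comprehensive
    Climate Index (CCI, an apparent temperature), accumulated into the
    Annual Thermal Load (ATL, the annual sum of daily CCI excesses above a
    30 degree Celsius comfort threshold) and a chronic-risk class, and each
    stress day is assigned to one of thirteen acute-by-chronic heat stress
    scenarios. Pain-Track tables (per-phase duration intervals and intensity
    probability distributions) then yield daily and annual hours of thermal
    discomfort by intensity with interval-arithmetic uncertainty, a shade
    mitigation comparison, and finishing-phase shade economics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
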