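Package: stemcast
Title: Stem-Diameter Sensing, Hybrid Forecasting, and Plant-Soil Irrigation Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for plant-centric irrigation timing from high-frequency
    dendrometer records. Cleans and aggregates 30-minute stem-diameter and
    greenhouse microclimate series; extracts diurnal water-status indicators
    (maximum daily shrinkage, daily increment, recovery time); decomposes the
    stem signal by seasonal-trend decomposition using Loess and forecasts it
    24 h ahead with a hybrid of deterministic component extrapolation and a
    gated recurrent network residual corrector; calibrates physiological
    stress thresholds from progressive-drought experiments by the
    growth-arrest criterion and statistical process control; and applies a
    dual-threshold (stem shrinkage plus soil water content) irrigation
    trigger. Includes a seeded synthetic greenhouse scenario generator so the
    whole pipeline is testable without field data.
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
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
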