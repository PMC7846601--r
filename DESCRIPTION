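Package: peatcarbon
Title: Carbon Accounting for Boreal Forested Peatlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying carbon stores in forested peatlands from
    peat-core and tree-ring data. Builds combined radiocarbon and lead-210
    chronologies (probabilistic calibration against an IntCal-style curve and
    the constant-rate-of-supply model), fits Monte-Carlo piecewise-linear
    age-depth models, detects macroscopic-charcoal fire horizons, converts
    bulk-density and loss-on-ignition profiles into carbon density, apparent
    carbon accumulation rates (CAR), long-term and recent apparent rates
    (LORCA, RERCA) and cumulative stocks, reconstructs annual tree biomass
    from ring-width series with allometric equations, and compares peat and
    tree carbon pools on a common post-fire timescale. Includes a
    forward simulator of complete synthetic sites with known ground truth
    for estimator-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
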