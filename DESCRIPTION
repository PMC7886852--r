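Package: corecc
Title: Comprehensive Carrying-Capacity Assessment for Coral Reef Islands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing the comprehensive carrying capacity of
    coral reef island social-ecological systems with paired pressure-support
    indicators arranged in a dimension / core-factor / indicator hierarchy.
    Per-indicator surplus ratios are combined by a root-mean-square vector
    aggregation into factor, dimension and overall carrying states, with an
    optional warning buffer near the full-load point. Support-end estimators
    are included for each core factor: multi-factor weighted raster overlay
    for suitable construction land, component sums for available water,
    a linear-programming total-maximum-load model for seawater assimilative
    capacity over a pollutant response field, area-weighted leaf-area index
    for terrestrial ecosystem services, and point-intercept / belt-transect
    estimators for coral cover and reef-fish density. A synthetic-data
    generator produces every input class with known ground truth, and the
    Zhaoshu Island 2017 case study ships as a built-in fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
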