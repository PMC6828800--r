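Package: minset
Title: Minimum-Set Conservation Prioritization and the Value of Cost and
    Biodiversity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying when land-cost data and biodiversity-feature
    data each improve the efficiency of spatial conservation prioritization.
    Implements minimum-set reserve selection as a binary integer linear
    program (monetary-cost and unit-count objectives), a cheapest-first
    C-rank baseline, occupancy-threshold filtering, aggregation of
    fine-resolution layers to planning units, an additive rescaling of the
    cost layer that fixes the ratio of benefit to cost coefficients of
    variation, and cost-benefit curve efficiency metrics (area under the
    curve and fractional gains between data-inclusion scenarios). Includes a
    seeded synthetic-landscape generator calibrated to the statistical
    structure of Pacific Northwest bird occupancy and cadastral land-value
    layers, so the full analysis is reproducible without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
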