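Package: O3Yield
Title: Surface-Ozone Exposure and Crop Yield Loss Under Emissions Scenarios
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An exposure-to-impact pipeline for quantifying the effect of
    surface-ozone changes on crop production. Hourly gridded ozone fields
    from two emissions scenarios are reduced to the AOT40 cumulative
    exposure index over a growing-season window, aggregated to county
    level by exact polygon-cell area weighting, converted to relative
    yield loss through a linear dose-response function, and valued in
    bushels and dollars. Scenario differencing, regional range summaries
    and domain-wide totals mirror the bookkeeping used in county-level
    ozone crop-damage assessments. A synthetic-data module generates
    hourly fields with a photochemical diurnal cycle, spatially correlated
    noise and regionally signed scenario deltas, together with county
    tessellations and production totals, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    ncdf4
Suggests:
    testthat (>= 3.0.0),
    sp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
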