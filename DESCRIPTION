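Package: cumulex
Title: Cumulative Extreme-Event Mapping and Species Exposure on Gridded Daily Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects discrete extreme events (marine and land heatwaves,
    extreme winds at sea and on land, extreme precipitation) on daily
    gridded environmental fields using a seasonally varying percentile
    climatology, builds per-pixel cumulative intensity, duration and
    frequency layers via min-max normalized stacking, estimates per-pixel
    least-squares trends of annual event metrics with
    positive-and-significant filtering, and ranks the exposure of species
    distribution hotspots to the resulting cumulative layers. Includes a
    synthetic-data generator (seasonal cycle, AR(1) noise, level trends,
    injected episodes, polygonal hotspots) so the full chain is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
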