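Package: vmekde
Title: Kernel Density Delineation of Significant Concentrations of
    Benthic Indicator Taxa from Trawl Survey Biomass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies "significant concentrations" (candidate vulnerable
    marine ecosystems) of aggregating benthic taxa -- sponge grounds, sea
    pen fields, gorgonian coral forests -- from research-vessel trawl
    survey point-biomass records.  Provides Kolmogorov-Smirnov threshold
    ladders to decide when catches from different gears and tow durations
    are combinable, biomass-weighted quadratic (Epanechnikov) kernel
    density surfaces on a raster grid, polygonization of the surface at
    successively decreasing biomass thresholds into threshold-area curves,
    and an auditable criteria engine that nominates (or rejects) the
    aggregation-defining biomass threshold.  A seeded Thomas-process scene
    generator with lognormal catch weights supports end-to-end validation
    against known aggregation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    optparse
Config/testthat/edition: 3
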