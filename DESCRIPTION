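Package: planktotype
Title: Plankton Community Types from Co-Occurrence Networks and Ocean-Color Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Delineates plankton community types from an OTU co-occurrence
    network using a weighted edge-satisfaction index, trains multiclass
    classifiers that predict those types from 17 satellite-derived ocean-color
    and temperature parameters with leave-one-out and spatially buffered
    cross-validation, and projects community-type distributions and long-term
    area trends (seasonal Mann-Kendall test, seasonal Theil-Sen slope) over
    gridded monthly feature series. Includes a synthetic-data generator that
    emulates rarefiable metabarcoding read counts with planted co-occurring
    OTU modules, satellite features driven by a latent environmental gradient,
    and spatially autocorrelated sampling locations, so every stage of the
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
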