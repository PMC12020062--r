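Package: tox5r
Title: Automated High-Throughput Screening Toxicity Scoring, Ranking and
    FAIR Serialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automated processing of 384-well plate high-throughput
    screening (HTS) toxicity campaigns. Reads plate-reader and imaging
    well-summary files, annotates wells with material, dose, time, replicate
    and cell-line metadata from a template workbook, recalculates doses
    between mass and particle-surface-area concentration units, applies
    endpoint-specific normalization and cleaning (percent of plate-wise
    controls with interquartile-range outlier removal, 0-h baseline
    correction, DAPI-based imaging artifact rules, caspase cell-loss
    normalization), computes dose-response metrics (first statistically
    significant effect dose at 2SD/3SD cutoffs, area under the
    effect-log-dose curve, maximum effect), combines them into transparent
    weighted Tox5 toxicity scores with bootstrap confidence intervals on
    scores and ranks, groups materials by bioactivity with agglomerative
    clustering and multiscale-bootstrap (AU/BP) cluster significance, and
    serializes raw and processed layers into a single hierarchical
    NeXus-style HDF5 file. A synthetic campaign generator emulating the
    plate design, noise and imaging artifacts of real screens makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    cluster,
    dplyr,
    jsonlite,
    readr,
    rhdf5,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
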