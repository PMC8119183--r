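Package: cytobarcode
Title: Combinatorial Live-Cell Barcoding Design and Debarcoding for Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing k-of-n combinatorial live-cell barcoding
    schemes for mass cytometry (CyTOF), simulating barcoded single-cell event
    data with known ground truth, reading and writing FCS 3.0/3.1 list-mode
    files, preprocessing events (DNA/event-length cell gating, viability
    gating, arcsinh transformation, percentile rescaling), debarcoding
    multiplexed batches by separation-threshold assignment or hierarchical
    Boolean gating, and reporting capture rates, per-barcode yields and
    ground-truth concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
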