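Package: dendromap
Title: Functional Imaging Analysis of Dendritic Spines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of in vivo two-photon movies of dendrites:
    phase-correlation motion correction with stable-chunk initialization and
    safeguarded shift interpolation, correlation-based segmentation of
    dendritic spine and shaft regions of interest, cross-session rigid
    alignment of feature maps by iterative closest point, spine turnover
    classification (lost / retained / gained), subtraction of
    back-propagating action potential contamination from spine signals, and
    stimulus/behavioral response analysis (constrained two-peak Gaussian
    orientation tuning, event-triggered averages with trial-type grouping).
    Includes a ground-truthed synthetic-data generator so the whole pipeline
    is testable without imaging data, plus readers/writers for multipage
    TIFF stacks, raw binary movies with JSON headers, and CSV stimulus
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    jsonlite,
    stats,
    graphics,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
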