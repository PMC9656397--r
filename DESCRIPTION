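Package: colonymorph
Title: Morphological Portraits of Pluripotent Stem-Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the morphology of human pluripotent stem-cell (hPSC)
    colonies and their cells from labeled segmentation images: seven shape
    descriptors (area, perimeter, minor axis, maximal and minimal Feret
    diameters, shape factor, and the area of intercellular space), time-binned
    dynamics summaries, two-way line-by-phenotype analysis of variance,
    normality-gated two-group comparisons, cross-validated phenotype
    classification with exhaustive predictor-subset enumeration and a
    per-parameter importance measure, minimal-model selection, and relative
    gene-expression analysis from qPCR cycle thresholds (2^-ddCt) with a
    reference-gene stability screen. Includes a seeded synthetic-data
    generator for labeled colony images, per-colony/per-cell feature tables,
    and Ct panels, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    MASS,
    nnet,
    car,
    nortest,
    EBImage,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
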