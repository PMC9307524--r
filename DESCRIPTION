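Package: periphytonr
Title: Synthetic Periphyton Assembly Design and Biofilm Image Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for designing and characterising synthetic
    freshwater periphyton (benthic phototrophic biofilm) communities. Implements
    optical coherence tomography (OCT) B-scan morphometrics (substrate interface
    detection, binarisation, mean biofilm thickness, relative roughness
    coefficient, internal porosity), Huang fuzzy-entropy thresholding with
    particle analysis for surface-colonisation coverage, effective photosystem II
    quantum yield from paired chlorophyll-fluorescence measurements, logistic
    growth-kinetics fitting with growth-group classification and sequential
    inoculum planning, and count-table operations (rarefaction, relative
    abundance, succession tracking). Ships seeded synthetic-data generators with
    known ground truth for every stage, so the full pipeline is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
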