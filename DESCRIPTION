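Package: arteryct
Title: Quantification of Arterial Collagen from Contrast-Enhanced Micro-CT and Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying collagen in arterial tissue from
    contrast-enhanced micro computed tomography (CE-uCT) and paired
    picrosirius-red histology. Converts stored CT pixel values to Hounsfield
    Units from DICOM rescale metadata, segments the vessel wall into lumen,
    intima, media and adventitia by per-layer HU intervals and seeded region
    growing, measures mean HU in internal- and external-media regions of
    interest, computes the polarized-light collagen-content statistic from
    brightfield plus dual polarized-light image triplets, applies a
    volume-based HU normalization, and correlates normalized HU with
    histological collagen content. Ships a synthetic vessel-phantom generator
    with known ground truth so the whole pipeline is testable without any
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    pracma,
    png,
    tiff,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
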