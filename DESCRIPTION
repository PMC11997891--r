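Package: spectrohist
Title: Stain-Free Infrared Spectral Histopathology of Pancreatic Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pixel-level pathology classification of
    hyperspectral FT-IR absorbance images of pancreatic tissue. Provides a
    synthetic phantom generator for mouse cohorts, Minimum Noise Fraction
    (MNF) denoising, region-local rubber-band (lower convex hull) baseline
    correction, spectral band metrics (maximum, center of gravity,
    integrated area) normalized to the Amide I band, random-forest
    classifiers in a detailed seven-class and a rapid three-class
    configuration, leave-one-mouse-out validation, majority filtering of
    prediction maps, and tissue-level screening via ROC analysis of
    pathology pixel counts with Hanley-McNeil standard errors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
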