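Package: constrictr
Title: Tissue-Scale Quantification of Apical Constriction from Cell and
    Junction Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies epithelial apical constriction during neural tube
    closure from tracked-cell and tracked-junction tables: per-track
    smoothing and standardization, mosaic crispant genotype calling from a
    membrane tracer, medial and junctional intensity measurement on label
    images, junction length correction for z-displacement, axis-referenced
    junction orientation, stable T1 neighbor-exchange detection, and the
    statistical comparisons used for such data (two-sample
    Kolmogorov-Smirnov, the Peacock two-dimensional Kolmogorov-Smirnov test
    with permutation p-values, and Pearson correlation). Includes a
    synthetic mosaic-epithelium generator with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
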