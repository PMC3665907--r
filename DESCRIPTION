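Package: coactmeta
Title: Coordinate-Based Meta-Analytic Connectivity Modeling and Seed-Based
    Resting-State Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Activation likelihood estimation (ALE) over coordinate databases
    of neuroimaging experiments, meta-analytic connectivity modeling (MACM)
    conditioned on seed regions, permutation-based co-activation difference
    and minimum-statistic conjunction analyses, seed-based resting-state
    correlation with nuisance regression and band-pass filtering, and
    forward/reverse functional decoding of seeds against task labels.
    Ships synthetic-data generators with planted ground truth so that every
    stage of the pipeline can be exercised and calibrated end-to-end without
    access-restricted imaging databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
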