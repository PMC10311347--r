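Package: dtitransfer
Title: Deep Transfer Learning for Ligand-Based Drug-Target Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curates ChEMBL-style bioactivity tables into balanced
    family-level activity classification datasets, pre-trains a two-hidden-
    layer feed-forward classifier on a data-rich source protein family, and
    transfers it to a small target-family dataset via full fine-tuning,
    frozen feature-transformer re-training, or a shallow SVM head on frozen
    penultimate features. Includes Butina leader clustering with chemical-
    series-disjoint splitting, controlled balanced subsampling across
    training-set sizes, an MCC-centric benchmark harness with from-scratch
    and zero-shot baselines, and a synthetic multi-family task generator
    with controllable cross-family signal overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineOB,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
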