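Package: mscmorph
Title: Label-Free Morphology-Based Prediction of Mesenchymal Stromal Cell
    Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the differentiation potentials (osteogenic, adipogenic,
    chondrogenic) and population doubling time of cultured human bone
    marrow-derived mesenchymal stromal cells from label-free phase-contrast
    images taken during the first four days of expansion culture. Provides a
    seeded synthetic-data generator for images, stained-culture fixtures,
    cell counts and gene-expression tables; universal-threshold segmentation
    and nine-feature morphometry of cell objects; six population-distribution
    feature-conversion schemes (M-patterns) built from quantile statistics
    and between-time-point ratios; histochemical stain quantitation and
    population-doubling-time teacher signals; L1-penalised linear regression
    with leave-one-out cross-validated model selection; and a 36-model
    benchmark against a mean-predictor NULL baseline scored by scaled error
    rate and correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
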