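Package: tmegraph
Title: Spatial Tumor-Microenvironment Graph Features from H&E Histology for
    Chemotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step analysis of annotated H&E histology slides. Step one
    partitions pathologist-annotated regions into 224x224 tiles, normalizes
    stain color, extracts 80 engineered texture features (GLCM, Gabor, LBP,
    Tamura, lower- and higher-order histogram) from the hematoxylin channel,
    and classifies tiles into 16 tissue classes plus background under
    stratified k-fold cross-validation. Step two assembles predicted tile
    labels into spatial histology maps, builds tumor-microenvironment graphs
    over tile-cluster centroids for every unordered pair of tissue classes,
    derives 20 graph features per pair (texture averages, local node
    configuration, global connectivity), ranks features with ReliefF, and
    predicts patient-level response to neoadjuvant chemotherapy (pCR versus
    residual disease) under leave-one-out cross-validation. A synthetic-data
    module generates texture tiles, annotated slides, and patient cohorts
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    polyclip,
    png,
    rpart,
    stats,
    utils,
    grDevices
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
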