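Package: mdnet
Title: miRNA-Disease Association Prediction from Heterogeneous Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts microRNA (miRNA)-disease associations by integrating
    protein-coding gene (PCG) interaction networks with miRNA-PCG and
    disease-PCG association profiles. Association profiles are enriched by
    degree-normalised message passing over the directed PCG functional
    interaction network, filtered with ReliefF feature selection supervised
    by disease ontology categories, embedded with a structural deep network
    embedding (SDNE) autoencoder over the heterogeneous miRNA-PCG-disease
    graph, and classified with a random forest over concatenated structural
    and biological features (miRNA family, ontology-based disease semantic
    similarity). Includes a seeded synthetic-data generator with a planted
    association mechanism, transductive and inductive evaluation splits, and
    ranking metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
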