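Package: bacppi
Title: Prediction and Characterization of Bacterial Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale prediction of bacterial protein-protein
    interaction (PPI) networks by interolog transfer and domain-domain
    interaction (DDI) inference, followed by network characterization:
    topology statistics and power-law degree-exponent estimation, exact
    minimum dominating sets for controllability analysis, COG-pair
    enrichment heat maps under a binomial null, GO semantic-similarity and
    transcription-correlation validation against degree-preserving random
    networks, condition-specific subnetwork dynamics from RPKM profiles,
    and protein-complex detection with functional-category entropy scoring
    and module-assisted annotation of uncharacterized proteins. A seeded
    synthetic-world generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
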