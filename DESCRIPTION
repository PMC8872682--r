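Package: herbrec
Title: Herb Recommendation from Symptom Knowledge Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a symptom network from a typed herb-symptom knowledge
    graph (word disassembly of symptom terms, synonymy, and metapath-derived
    symptom-symptom relations), learns node embeddings with random-walk
    skip-gram (DeepWalk/node2vec) or one-hot encoding, maps arbitrary
    symptom terms -- including terms never seen in the knowledge base -- onto
    concept subnetworks, fuses the mapped concepts into per-symptom feature
    vectors, and trains an attention-convolution multi-label model that
    ranks herbs for a patient's symptom set. Includes micro-averaged Top-K
    evaluation, a prescription-symptom similarity correlation analysis, and
    a latent-group synthetic data generator for end-to-end signal-recovery
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
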