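Package: protgo
Title: Protein Function Prediction with Sequence Similarity and Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) functions for protein sequences by
    combining bitscore-weighted annotation transfer from sequence-similarity
    hits with a multi-kernel one-dimensional convolutional neural network
    trained on amino-acid sequences. Includes an OBO ontology parser with
    true-path-rule annotation propagation, evidence-code filtering,
    information-content estimation, hierarchy-consistent post-processing of
    prediction scores, CAFA-style protein-centric evaluation (Fmax, Smin,
    AUPR over a 0.01 threshold sweep), and a synthetic benchmark generator
    (toy ontologies, motif-implanted sequences, simulated similarity hits)
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
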