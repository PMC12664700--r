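Package: niffindr
Title: Nif Protein Prediction from Proteomes with Spaced-Word Projections
    and Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free identification and classification of
    nitrogen-fixation (Nif) proteins in protein FASTA files. Amino-acid
    sequences are encoded as fixed-length SWeeP vectors (spaced-word
    counting under a binary mask followed by a seeded orthonormal random
    projection, 1369 coordinates by default) and scored against one
    binary neural-network classifier per Nif class: a 5:3:1 multi-layer
    perceptron and a 51-basis radial basis function network, with the
    better model per class selected by F1 score and accuracy. Includes
    the full retrainable pipeline (redundancy reduction, 1:2 negative
    sampling, stratified 70/30 splits), a synthetic protein-family
    generator for end-to-end benchmarking, and evaluation tools
    (confusion matrices, per-class and macro metrics, class-count
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
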