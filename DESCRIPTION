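Package: mncr
Title: Multi-Encoding Neural Classification of Non-Coding RNA Classes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classification of non-coding RNA classes (lncRNA, miRNA, rRNA,
    snRNA, snoRNA, tRNA) from primary sequence and predicted secondary
    structure. Implements three encodings of an RNA molecule (ordinal
    sequence vectors, a combined nucleotide-substructure alphabet, and
    hashed weighted graph-feature vectors over windowed structure
    representatives), four neural architectures including a late-integration
    merged model, the training and ten-fold cross-validation protocol,
    dataset construction rules (length filtering, identity-based redundancy
    reduction, balanced splits, fine-grained relabeling), a benchmark
    harmonization pipeline, and a synthetic ncRNA generator so the whole
    stack runs at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
biocViews: Classification, Sequencing, StructuralPrediction, RNASeq
RoxygenNote: 7.3.3
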