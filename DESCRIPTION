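Package: barcodeval
Title: Evaluation of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating DNA barcode reference
    libraries, with an emphasis on the plant ITS2 marker. Provides a
    sequence simulator with a known taxonomic hierarchy, profile-based
    trimming of conserved 5.8S/28S flanking motifs, Kimura 2-parameter
    distances with pairwise deletion and rank-level summaries, per-species
    barcoding-gap analysis, neighbor-joining trees with bootstrap support
    and tree-based species discrimination, and similarity-based best-match
    identification with the standard correct/ambiguous/incorrect
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
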