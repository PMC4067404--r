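Package: tissuerep
Title: Tissue-Level Antibody Heavy-Chain Repertoire Annotation and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for expressed antibody heavy-chain variable-gene
    repertoires sequenced from tissue RNA pools. Provides a germline V(D)J
    reference container, a synthetic repertoire simulator with per-read ground
    truth (V(D)J recombination, somatic hypermutation, codon-length
    hypermutation-associated indels, pyrosequencing homopolymer errors and
    defective reads), a local-alignment annotator with codon-based homopolymer
    error correction, antibody-specific quality filters with duplicate
    collapse, repertoire summary metrics (gene-family usage, mutation
    profiles, HCDR3 physicochemistry, positional indel maps), and cross-sample
    comparison via complete-linkage clustering on Pearson correlation
    distances and negative-binomial GLM likelihood-ratio tests of differential
    V(D)J usage with Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    ape,
    jsonlite
Config/testthat/edition: 3
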