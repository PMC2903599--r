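Package: hierfold
Title: Hierarchical Comparative Prediction of Joint RNA Structures and
    RNA-RNA Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts joint secondary structures and RNA-RNA interactions
    from two multiple sequence alignments of homologous RNAs with matched
    taxa. Reliable intra-molecular base pairs are first selected from a
    combined phylogenetic SCFG posterior and per-sequence thermodynamic
    ensemble probabilities; the selected partial structures are then
    constrained single-stranded while the concatenated alignment is scored
    by constrained expected accuracy, so that inter-molecular helices
    (including kissing hairpins, i.e. pseudoknots between intra- and
    inter-molecular pairs) can be decoded with a Nussinov-style maximum
    expected accuracy algorithm. Includes a seeded synthetic alignment-pair
    generator with planted covarying interaction sites for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
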