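Package: rad2b
Title: Whole-Genome Phylogeny from Predicted Type IIB Restriction Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates Type IIB restriction digestion (2b-RAD) of genome
    assemblies, builds representative per-genome fragment sets, counts
    identical and near-identical shared fragments between genome pairs under
    a mismatch tolerance, converts sharing ratios to a log-ratio evolutionary
    distance, and reconstructs per-enzyme neighbor-joining trees together
    with a majority-rule consensus annotated with per-branch enzyme support.
    Includes a sequence simulator that evolves genomes along a known tree
    under the Jukes-Cantor model so that topology recovery can be tested
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
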