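Package: anomito
Title: Comparative Mitogenomics of Anomuran Crustaceans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of anomuran (hermit crab, king
    crab, squat lobster) mitochondrial genomes: base composition and AT/GC
    strand-asymmetry skews, canonicalization and typing of circular signed
    gene orders with breakpoint distances against the pancrustacean ground
    pattern, depth-matched Ka/Ks (NG86) selection analysis with sliding
    windows and Fisher exact tests, control-region characterization (tandem
    repeats, microsatellites, inverted repeats, motif blocks, minimum-free-
    energy secondary structure), and family-wise association between
    control-region folding free energy and habitat depth. A deterministic
    synthetic-data generator provides mitogenomes, control regions and codon
    pairs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
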