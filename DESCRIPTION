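Package: selcontrast
Title: Codon-Model Contrasts of Selection Across Lineages with Divergent Sperm Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative analyses of protein-coding
    sequence evolution across lineages with contrasting trait states. Implements
    tree-based ortholog extraction from homolog gene trees (rooted-ingroup and
    maximum-inclusion algorithms with long-tip and deep-paralog pruning), codon
    alignment preparation (back-translation, reliability-score column trimming,
    sequence and alignment filtering), Goldman-Yang style codon substitution
    models with branch partitions, branch-site mixtures and a selection-intensity
    exponent (RELAX-style), empirical-Bayes site posteriors, and the statistical
    contrast layer: likelihood-ratio tests, Storey q-values, Kruskal-Wallis and
    Dwass-Steele-Critchlow-Fligner nonparametric contrasts, chi-square tests
    against expected annotation-group distributions, omega-pattern
    classification, independent trait-transition counting, Nei-Gojobori pairwise
    dS and Karlin-Mrazek codon-usage bias diagnostics. A synthetic-data module
    generates species trees with labelled trait transitions, homolog trees with
    paralogs, and codon alignments evolved under all implemented regimes, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
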