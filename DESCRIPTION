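Package: funtron
Title: Predicting Functional Introns from Positional Conservation of Gene Architecture
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for identifying human introns likely to harbor functional
    sequence elements from the evolutionary conservation of their position
    along the coding sequence. Gene architectures of orthologous transcripts
    are encoded as ternary intron presence-absence patterns over a dated
    phylogeny, summarised by thirteen evolutionary and positional features
    (Sankoff parsimony costs under asymmetric gain/loss pricing, Dollo origin
    age, clade presence indicators, a two-state gain/loss Markov pattern
    log-likelihood, and median CDS position), and classified with a logistic
    model whose observed functionality labels are treated as a one-sided noisy
    version of the hidden true labels, trained by Expectation-Maximization.
    Includes estimators for the label-completeness parameter and for the
    probability that an unlabeled intron is functional, a Fisher-discriminant
    visualisation, a four-technique feature-importance battery, enrichment and
    permutation tests, and a synthetic-data simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
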