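Package: covtandem
Title: Multi-Site Covariant Pattern Detection and Sequence Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects covariant mutations in multiple sequence alignments
    using site-residue elements: an independent pair model scores every
    pair of elements at distinct aligned sites with a co-occurrence purity
    statistic, and a correlated tandem model joins confirmed pairs into
    groups and prunes weakly associated elements by their average
    association degree to harvest multi-site covariant patterns. Patterns
    act as population signatures: sequences are clustered by a loose
    pattern-match rule and classifiers are evaluated by sensitivity,
    specificity and accuracy with stratified k-fold cross-validation. A
    seeded synthetic-alignment generator with planted covariant structure
    supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
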