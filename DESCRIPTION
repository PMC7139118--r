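Package: cneduo
Title: Paralogous Conserved Noncoding Element Analysis in Duplicated Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a duplicated conserved noncoding element (CNE)
    shared by two paralogous, syntenic gene clusters that arose by whole-genome
    duplication, modelled on the HOTAIR / ncHOXD11 element pair. Provides
    homology scanning with synteny-based cluster assignment and cross-species
    presence/absence matrices; orientation-aware RNA-RNA complementarity
    profiling and detection of compensatory substitution events on a species
    tree by Fitch parsimony; intron-retention quantification from spliced read
    alignments; enhancer-state calling (closed, poised, active) from CAGE tag
    clusters and chromatin signal tracks, including divergent enhancer-RNA pair
    detection at nucleosome-scale spacing; and cis/trans co-expression
    correlation on co-expressed sample subsets. A seeded synthetic-data
    generator emulates all required inputs with a ground-truth ledger so every
    stage is testable without consortium downloads, and a single-config pipeline
    runs the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
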