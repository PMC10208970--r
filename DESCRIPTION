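Package: trioTriage
Title: Trio Genome Triage and Brain Co-Expression Prioritization for
    Candidate Gene Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for candidate-gene discovery in trio genome sequencing
    studies of severe childhood speech disorder and related
    neurodevelopmental conditions. Implements site and genotype quality
    filtering, population-frequency and inheritance-model filtering
    (de novo, inherited, X-linked, compound heterozygous), classification
    of predicted loss-of-function and damaging missense variants, a
    two-stage gene-panel shortlisting strategy with confidence tiers, a
    developmental-brain co-expression statistic with a Monte-Carlo null,
    and connectivity-score gene prioritization with Benjamini-Hochberg
    false discovery rate control. Ships seeded simulators for annotated
    trio cohorts, gene panels and block-structured expression matrices so
    every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: VariantAnnotation, GeneExpression, Network, Software
RoxygenNote: 7.3.3
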