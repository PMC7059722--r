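Package: capture3c
Title: Multiplexed dCas9-Capture Chromatin Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical analysis of multiplexed dCas9-capture
    proximity-ligation (3C) sequencing data. Converts aligned read pairs into
    deduplicated, bait-assigned pair-end tags (PETs) with self-ligation and
    off-target filtering; calls long-range chromatin interactions per bait
    against a distance- and size-matched sampled negative-binomial background
    using a Bayes factor; quantifies interaction signal as PETs per kilobase
    per million read pairs (PPKM); scores super-enhancer hierarchy with an
    H-score and gamma-fit hub-enhancer classification; classifies
    promoter-centric interactions into enhancer-promoter and other contacts
    and integrates them with time-course expression. A seeded synthetic-data
    generator produces bait-anchored contacts with distance-decay background,
    planted loops and library artifacts so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    MASS,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
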