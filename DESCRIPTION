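Package: natscape
Title: Genome-Wide Analysis of Natural Antisense Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and characterisation of natural antisense
    transcript (NAT) pairs from genome annotation and expression data.
    Classifies cis-NAT pairs into orientation subtypes (convergent,
    divergent, containing, nearby), finds trans-NAT pairs by
    reverse-complement local alignment with a duplex bubble rule, calls
    NAT-siRNAs from filtered small-RNA alignments, computes the
    overlap-region small-RNA enrichment score with a one-tailed paired
    t-test, classifies histone-modification pair patterns against
    randomized non-NAT nulls, measures pairwise DNA-methylation distance
    (D_mC = 1 - r) per sequence context, and builds the NAT coexpression
    network. Ships a synthetic-data generator that plants NAT geometry,
    overlap-region siRNA enrichment and epigenetic pair concordance so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
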