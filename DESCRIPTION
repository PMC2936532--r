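Package: phosregulon
Title: Regulatory Genomics of the Phosphate-Starvation Transcriptional Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the P1BS cis-element (GNATATNC) to PHR1-dependent
    phosphate-starvation gene induction. Provides degenerate IUPAC motif
    scanning, partitioning of gene neighbourhoods into promoter, UTR, coding,
    intron and downstream regions, region-resolved motif enrichment with
    chi-square significance, sliding-window motif-dosage versus inducibility
    curves, cross-stress specificity summaries, distance-constrained motif
    co-occurrence tests with analytic and permutation nulls, fold-change/FDR
    responsive-set and direct-target calling, hypergeometric gene-set overlap
    statistics, and a seeded synthetic genome plus expression generator with
    planted binding sites for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
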