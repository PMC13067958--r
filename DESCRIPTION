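Package: probioscreen
Title: Probiotic Marker Screening and Comparative Genomics of Lactic Acid
    Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for reclassified
    Lactobacillus (Lactobacillaceae) genomes: assembly quality gating on
    completeness, contamination, contig count and N50; regular-expression
    screening of CDS annotation text against a curated probiotic marker
    panel with Smith-Waterman alignment confirmation; threshold-based
    antimicrobial-resistance and virulence-factor retention plus
    biogenic-amine and hemolysin term screens; bacteriocin locus
    consolidation, subclass assignment and species-level summaries;
    CAZyme hit filtering and family aggregation; and a greedy ortholog
    clustering pan-genome with soft-core/shell/cloud partitioning and
    accumulation curves. A seeded synthetic-cohort generator plants
    markers, bacteriocin loci and safety genes with known ground truth so
    every stage can be exercised end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
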