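Package: goatcnv
Title: Read-Depth CNV Calling and Synteny-Based Scaffold Anchoring for
    Wild-vs-Domestic Goat Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed read-depth copy-number-variation analysis for
    comparisons of wild and domestic goat cohorts, together with
    reference-guided scaffold anchoring. Computes 200-bp sliding-window
    read-count tracks from alignments or per-base depth tables, calls CNV
    gain and loss regions with a five-of-seven sequential-window rule,
    classifies candidate deleted and duplicated genes from cohort CNV
    ratios, estimates copy number from qPCR Ct tables by the
    delta-delta-Ct method, and anchors scaffolds onto chromosomes from
    whole-genome alignment hits (100-kb hit clustering,
    longest-more-than-twice-second placement, AGP/FASTA pseudo-chromosome
    output, and a Y-chromosome variant with repeat-aware gap merging). A
    synthetic-data module generates genomes, depth tracks with known
    copy-number truth, fragmented assemblies with known placements, and
    Ct tables, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
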