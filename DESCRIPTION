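Package: ashmscan
Title: Genome-Wide Discovery of Aberrant Somatic Hypermutation Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies recurrent targets of aberrant somatic hypermutation
    (aSHM) from cohort somatic SNV calls. Derives per-gene SHM-target windows
    downstream of transcription start sites, computes base-composition
    corrected SHM signature statistics (WRCY/RGYW hotspot-motif enrichment,
    C:G versus A:T site bias, transition excess) with one-sided exact tests,
    combines them into a composite SHM indicator, stratifies targets by
    mutation density, profiles mutation distance to the TSS, links mutation
    status to mRNA abundance, and cross-tabulates mutations with genomic
    rearrangements. Ships a fully parameterized synthetic-cohort simulator
    of the AID mutational process so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
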