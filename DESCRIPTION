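Package: traelr
Title: Analysis and Simulation of TrAEL-Seq DNA 3' End Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of Transferase-Activated End Ligation
    sequencing (TrAEL-seq) data, which maps single-stranded DNA 3' ends
    genome-wide at base-pair resolution. Implements read preprocessing
    (UMI extraction, sample-barcode demultiplexing, capped poly-T trimming),
    UMI-aware deduplication of aligned reads, strand-specific single-nucleotide
    3'-end count tracks with windowed quantitation and masking, replication
    fork directionality (read polarity) profiles with origin and termination
    calling, group comparison of polarity tracks, detection of fork-stall
    peaks and of interval enrichment over a sampled background, and a
    ground-truth read simulator (restriction digests with degenerate
    recognition sites, TdT A-tails, replication-fork and DSB-hotspot end
    distributions, exact read mapping) so that every pipeline stage can be
    verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
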