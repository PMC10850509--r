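Package: loopstitch
Title: Stitched Enhancer Region Calling and HiChIP Loop-Weighted Target Gene Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regulatory-genomics analysis of a chromatin-bound
    transcription-factor complex: calling highly enriched ("superenhancer-like")
    regions from stitched ChIP-seq peaks with a rank-curve slope-1 inflection
    cutoff, classifying HiChIP enhancer-promoter loops by cofactor occupancy,
    computing loop-weighted per-gene aggregate enrichment scores, a
    co-immunoprecipitation proteomics enrichment score with peptide-level
    moderated statistics, and target-gene association statistics
    (peak-count expression bins, overlap chi-square versus random placement,
    fold-change correlations, responsive-gene selection, and principal-component
    contributor selection). Includes a synthetic-data generator that plants
    known ground truth so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    limma,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
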