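Package: tdmdscan
Title: Nomination of Target-Directed microRNA Degradation Trigger Sites
    from AGO-CLASH Chimeras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale, fully deterministic pipeline for nominating
    candidate trigger sites of target-directed microRNA degradation (TDMD)
    from AGO-CLASH / chimeric eCLIP sequencing reads. Converts raw chimeric
    reads into deduplicated miRNA:target assignments in transcript space
    (UMI extraction, adapter trimming, snoRNA-like contaminant removal,
    miRNA segment calling, ungapped target mapping, UMI deduplication),
    assembles target-site clusters with transcript-region annotation and
    per-base conservation, predicts miRNA:target duplexes by
    nearest-neighbor dynamic programming, classifies seed matches
    (6mer/7mer-A1/7mer-m8/8mer), applies a stringent multi-criterion filter
    (seed match, noncoding location, bounded central bulge, consecutive
    3'-end pairing, positive conservation), and ranks survivors by the
    minimum free energy of the duplex between the miRNA 3' region and the
    trigger flank. Includes a synthetic AGO-CLASH read generator with a
    ground-truth manifest for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stringi,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
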