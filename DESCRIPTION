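Package: pasmap
Title: Polyadenylation Signal Scanning and Antisense Complementarity
    Mapping for Transcript 3' Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies transcript 3' ends by polyadenylation signal (PAS)
    hexamer variants scanned in the terminal window of each transcript,
    matches downstream sequence elements (DSEs) against a thresholded
    sequence logo in genome-derived downstream windows, and detects
    antisense complementary regions among pools of lncRNA sequences by
    mismatch-tolerant k-mer mapping (k = 19-25, 0-2 mismatches) with BED
    output and interval merging. Includes a seeded synthetic-data module
    that plants PAS/DSE motifs at controlled rates and antisense blocks
    with exact mismatch counts, so every pipeline stage is verifiable
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
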