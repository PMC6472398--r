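Package: riboAsite
Title: A-Site and P-Site Offset Calibration for Ribosome Profiling by
    Integer Programming
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates the ribosome A-site on ribosome-protected mRNA
    fragments from Ribo-Seq experiments as a function of fragment size
    and 5' end reading frame. Per-gene offsets are found by maximizing,
    over frame-preserving shifts, the number of footprint reads falling
    between the second codon and the stop codon of the coding sequence,
    and are aggregated into a transcriptome-wide offset table with
    bootstrap confidence intervals, coverage-trend, threshold-robustness
    and cross-dataset consistency diagnostics. Includes a stochastic
    translation simulator that generates artificial Ribo-Seq profiles
    with known ground-truth offsets for validation, baseline offset
    methods for comparison, A-site profile construction, metagene
    summaries, and permutation tests for ribosome pausing at PPX/XPP
    polyproline motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
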