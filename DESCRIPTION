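Package: rilrec
Title: Recombination Rate Landscapes and Hotspot Detection from RIL Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds Marey-map recombination-rate landscapes from biparental
    recombinant inbred line (RIL) SNP genotypes and calls recombination
    hotspots and coldspots. Covers marker quality control (missingness,
    segregation distortion, duplicate collapse), two-point linkage mapping on
    the physical marker order with the Haldane-Waddington RIL correction,
    cubic-spline and windowed recombination-rate estimation in cM/Mbp,
    sliding-window peak calling with Tukey outlier filtering stratified by
    chromatin class, cross-population hotspot comparison, logistic-regression
    association with genomic features such as transposable elements, and
    fixed-motif scanning of hotspot flanking sequence with a permutation
    background. A forward simulator of F_k-derived RIL populations by single
    seed descent over a configurable piecewise recombination landscape
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
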