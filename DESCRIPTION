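Package: shallowcnv
Title: Copy-Number Variant Detection from Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copy-number gains and losses from shallow (0.1x-5x)
    whole-genome sequencing read depth. Per-base coverage, which at low
    coverage is strongly zero-inflated, is smoothed with a segment sliding
    window so that segment means are approximately normal; a two-sided
    CUSUM control chart on the log2 ratio of observed to expected depth
    delimits candidate CNV regions against a panel-of-normals baseline;
    each candidate is then re-scored with a single dynamic, region-sized
    window and classified as gain or loss. Includes a zero-inflated
    Poisson coverage simulator with implanted CNVs and an evaluation
    module scoring call sets against truth sets by reciprocal overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
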