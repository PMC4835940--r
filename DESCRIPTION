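Package: mmp2d
Title: Two-Dimensional Multiscale-Parser Compression of Surface EMG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lossy compression of surface electromyographic (SEMG) records
    rearranged as two-dimensional images, using a modified multidimensional
    multiscale parser (MMP): recurrent pattern matching against an adaptive
    multiscale dictionary, Lagrangian rate-distortion optimization of a
    segmentation tree, hierarchical HEVC-style intra prediction (33 angular
    modes, planar, and most-frequent-value), and context-adaptive arithmetic
    coding.  Includes the percentage-difference-sorting (PDS) and
    segmentation-by-similarity (SbS) preprocessing algorithms, matrix
    formation with exact inversion, PRD/CF evaluation with rate-distortion
    sweeps, a synthetic SEMG generator for isometric and dynamic protocols,
    a 16-bit PGM export hook for benchmarking external image codecs, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
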