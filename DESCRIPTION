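Package: overqc
Title: Reference-Free Quality Control for Long Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Quality control for long, error-prone sequencing reads
    (PacBio, Oxford Nanopore) that does not require a reference genome or
    Phred scores. Reads are sketched with canonical minimizers, read-to-read
    overlaps are detected and filtered, and each sampled read is classified
    as informative or "non-sense" (overlapping almost nothing else in the
    library) from its overlapping-partner count. The package estimates the
    dataset noise fraction with a confidence interval, per-read error rates
    from k-mer survival in overlaps, adapter-like terminal boundaries, and
    the usual descriptive statistics (length, N50, GC, mean quality,
    windowed sequence complexity), with ggplot2 figures and a
    machine-readable report. A synthetic-read simulator with full ground
    truth supports validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    Rsamtools,
    S4Vectors,
    data.table,
    graphics,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
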