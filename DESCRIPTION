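Package: ncarray
Title: Design and Expression Analysis of Custom Noncoding RNA Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to build and analyse custom spotted two-color microarrays
    for small noncoding RNAs. Covers selection of probe target regions from
    RNA-Seq coverage contigs, multi-criterion oligonucleotide design with
    single-mismatch control probes (DNA:RNA nearest-neighbor melting
    temperatures), print-tip blocked array layouts with octuplicate spotting,
    a generative two-color dye-swap hybridization simulator with known ground
    truth, and a differential-expression pipeline (background subtraction,
    print-tip local-regression and quantile normalization, PM>MM filtering,
    dye-swap linear models, empirical-Bayes moderated statistics and
    Benjamini-Hochberg correction).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
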