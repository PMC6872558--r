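Package: barcodegap
Title: Evaluation of DNA Barcode Markers for Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating candidate DNA barcode markers from aligned
    sequence data: per-marker sequence characteristics (GC content,
    conserved/variable/parsimony-informative sites, pairwise similarity),
    Kimura two-parameter pairwise distances, the six standard inter- and
    intraspecific divergence statistics (including theta, theta prime and
    coalescent depth), Wilcoxon signed-rank comparison of markers,
    barcoding-gap detection from distance distributions, marker
    concatenation, and neighbor-joining trees with column-bootstrap support
    and per-species monophyly assessment. A seeded sequence simulator
    generates species-labelled multi-marker alignments with known divergence
    structure so the whole pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
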