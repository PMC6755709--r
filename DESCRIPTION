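Package: cordtrack
Title: Clonal Barcode Tracking and Growth-Normalized Secretome Analysis
    for Umbilical Cord MSC Explant Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolutes lentiviral genetic barcodes from amplicon
    sequencing reads of serially induced mesenchymal stromal cell explant
    monolayers (MSC-EMs) grown from umbilical cord pieces, tracks clonal
    composition across induction cycles, and quantifies the activated MSC
    secretome normalized by the area under the exponential growth curve.
    Includes a synthetic-data module that simulates barcoded amplicon reads
    (sample tag, constant flanks, 15-nt fluorophore tag, 16-nt random
    barcode) with configurable substitution and indel errors, greedy
    error-correction clustering of barcode variants onto the most frequent
    sequence, clone-by-sample relative abundance matrices with
    tissue-shared clone classification, diversity statistics, and paired
    early-versus-late Wilcoxon comparison of per-cell cytokine secretion
    rates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    grDevices,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
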