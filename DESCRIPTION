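Package: markerdecon
Title: Cell-Type Composition Assessment for Bulk RNA-Seq Using
    Single-Cell Marker Gene References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses cell-type composition of bulk RNA-Seq samples from
    heterogeneous tissues using published single-cell RNA-Seq marker gene
    lists as a reference. Builds a unique-marker cell-type reference by
    removing genes shared between cell types, normalizes bulk count
    matrices by the trimmed mean of M-values (TMM) with an additive
    offset, annotates transcripts with cell types by official gene
    symbol, infers per-group cell-type presence and group-exclusive
    genes, and tests per-transcript group differences with multiple
    unpaired t-tests under the Benjamini-Krieger-Yekutieli two-stage
    false discovery rate procedure. Also provides per-group coefficient
    of variation analysis, principal component analysis with
    two-standard-deviation group ellipsoids, sequencing quality-control
    group comparisons, a synthetic-data generator with known ground
    truth, and a reproducible end-to-end pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
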