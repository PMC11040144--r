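Package: iceberg
Title: Exhaustive Identification of Binding Events from Many CUT&RUN Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements ICEBERG (Increased Capture of Enrichment By Exhaustive
    Replicate aGgregation), a replicate-aggregation strategy for CUT&RUN and
    related genome-wide binding assays. Many replicates are downsampled to equal
    depth and pooled into several aggregate tracks; peaks called on a majority of
    aggregates and supported by at least one individual replicate at relaxed
    stringency form an exhaustive reference peak set. The package provides a
    Poisson local-background peak caller with IgG control support, decay and
    build curves, polynomial saturation modelling with derivative-based plateau
    estimation, per-peak detection-probability groups, precision/recall/F1
    benchmarking of replicate strategies against the aggregated reference,
    chromatin-loop anchor statistics, and a seeded synthetic fragment generator
    with a planted occupancy-probability spectrum for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
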