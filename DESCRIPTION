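Package: tribescope
Title: Editing-Based Mapping of microRNA Target Transcripts in Bulk and
    Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects Argonaute-guided A-to-I RNA editing events from aligned
    RNA-seq reads and identifies microRNA target transcripts from them.
    Implements strand-aware mismatch calling with Phred and read-depth
    filters and known-SNP/known-editing site exclusion, per-3'UTR event
    aggregation with biotype filtering, regression-residual ranking of
    edited genes against a deaminase-only background, target-set comparison
    statistics (Jaccard, binomial overlap enrichment), derepression analysis
    after global microRNA inhibition (TMM normalization, fold-change ECDFs,
    and a reweighted ECDF-distance permutation test), positional concordance
    against binding-site data, and single-cell workflows (linker-read
    transfection calling, QC filters, cell-cycle module scores and phase
    assignment, spike-in pseudobulk normalization, and differential
    targeting across cell-cycle stages). A self-contained synthetic-data
    generator emulates the statistical structure of such experiments with
    ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    edgeR,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
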