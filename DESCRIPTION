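Package: rankatlas
Title: Cross-Platform Transcriptome Atlases via Rank Percentiles and
    Platform-Variance Gene Filtering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds integrated reference atlases of gene expression from
    heterogeneous collections of microarray and RNA-seq datasets. Each
    sample is transformed to rank percentile values, genes whose variance
    is dominated by profiling platform are removed using a fixed-effect
    analysis of variance, and a principal component atlas is fitted on the
    remaining genes. The package supports recursive refinement of the
    atlas on sample subsets, resampling-based assessment of cluster
    stability through the Jaccard H-index, linear mixed model diagnostics
    of class versus platform variance components, and linear projection of
    external bulk or pseudo-bulk aggregated single-cell profiles onto a
    fitted atlas. A configurable multi-platform expression simulator with
    known cell-type and platform effects is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, BatchEffect,
    PrincipalComponent, Clustering, SingleCell
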