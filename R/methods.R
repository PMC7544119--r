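#' @describeIn AtlasExperiment value kind of the assay ("raw" or
#'   "percentile").
#' @export
setMethod("valueKind", "AtlasExperiment", function(x) x@valueKind)

#' @describeIn AtlasExperiment the gene-by-sample assay matrix.
#' @export
setMethod("exprValues", "AtlasExperiment",
    function(x) assay(x, "exprs"))

#' @describeIn AtlasExperiment per-sample annotation as a data.frame
#'   (sample ids as row names).
#' @export
setMethod("sampleAnnotation", "AtlasExperiment",
    function(x) as.data.frame(colData(x)))

setMethod("show", "AtlasExperiment", function(object) {
    cat(sprintf("AtlasExperiment: %d genes x %d samples (%s values)\n",
        nrow(object), ncol(object), object@valueKind))
    if (ncol(colData(object)))
        cat("  annotation:", paste(colnames(colData(object)),
            collapse = ", "), "\n")
    invisible(NULL)
})

#' @describeIn AtlasModel ordered ids of the genes entering the PCA.
#' @export
setMethod("selectedGenes", "AtlasModel", function(x) x@selectedGenes)

#' @describeIn AtlasModel mean training percentile per selected gene.
#' @export
setMethod("geneMeans", "AtlasModel", function(x) x@geneMeans)

#' @describeIn AtlasModel components-by-genes loading matrix.
#' @export
setMethod("atlasLoadings", "AtlasModel", function(x) x@loadings)

#' @describeIn AtlasModel per-component variance of the training
#'   coordinates.
#' @export
setMethod("explainedVariance", "AtlasModel", function(x) x@explainedVariance)

#' @describeIn AtlasModel training-sample coordinates (samples x
#'   components).
#' @export
setMethod("trainingCoords", "AtlasModel", function(x) x@trainingCoords)

setMethod("show", "AtlasModel", function(object) {
    cat(sprintf(
        "AtlasModel: %d genes, %d components, %d training samples\n",
        length(object@selectedGenes), object@nComponents,
        nrow(object@trainingCoords)))
    cat(sprintf("  platform-variance threshold: %g\n", object@threshold))
    ev <- object@explainedVariance
    pct <- 100 * ev / sum(ev)
    cat("  explained variance (%):",
        paste(sprintf("%.1f", utils::head(pct, 5)), collapse = " "),
        if (length(pct) > 5) "..." else "", "\n")
    invisible(NULL)
})

#' @describeIn StabilityReport median of the per-cluster H-indices.
#' @export
setMethod("medianH", "StabilityReport",
    function(x) stats::median(x@perClusterH))

setMethod("show", "StabilityReport", function(object) {
    cat(sprintf(
        "StabilityReport: %s, %s, k = %d (%d resamples, %d skipped)\n",
        object@algorithm, object@scheme, object@k, object@nResamples,
        object@nSkipped))
    h <- object@perClusterH
    cat(sprintf("  H-index: median %.3f [min %.3f, max %.3f]\n",
        stats::median(h), min(h), max(h)))
    if (length(object@geneOverlapPct))
        cat(sprintf("  gene overlap %%: median %.1f [%.1f, %.1f]\n",
            stats::median(object@geneOverlapPct),
            min(object@geneOverlapPct), max(object@geneOverlapPct)))
    invisible(NULL)
})

#' Summarise stability reports as a data.frame
#'
#' @param reports a list of [StabilityReport-class] objects (one per k), as
#'   returned by [resampleStability()].
#' @return data.frame with one row per report: algorithm, scheme, k,
#'   median/min/max H, resample counts and gene-overlap summaries.
#' @export
stabilityTable <- function(reports) {
    if (is(reports, "StabilityReport")) reports <- list(reports)
    do.call(rbind, lapply(reports, function(r) {
        go <- r@geneOverlapPct
        data.frame(
            algorithm = r@algorithm, scheme = r@scheme, k = r@k,
            median_h = stats::median(r@perClusterH),
            min_h = min(r@perClusterH), max_h = max(r@perClusterH),
            n_resamples = r@nResamples, n_skipped = r@nSkipped,
            gene_overlap_median = if (length(go)) stats::median(go) else NA,
            gene_overlap_min = if (length(go)) min(go) else NA,
            gene_overlap_max = if (length(go)) max(go) else NA
        )
    }))
}
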