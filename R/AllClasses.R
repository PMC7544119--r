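#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   colData<-
NULL

#' AtlasExperiment: a gene-by-sample expression container
#'
#' Thin subclass of [SummarizedExperiment::SummarizedExperiment] holding a
#' single gene-by-sample assay (`"exprs"`) together with per-sample
#' annotation in `colData`. The `valueKind` slot records whether the assay
#' contains raw abundances (RPKM, microarray intensity, counts) or rank
#' percentile values on \[0, 1\].
#'
#' Row names are gene identifiers (opaque strings, Ensembl ids expected) and
#' column names are sample identifiers; both must be unique. Readers and the
#' constructor preserve the input gene and sample order.
#'
#' @slot valueKind character, `"raw"` or `"percentile"`.
#' @export
setClass("AtlasExperiment",
    contains = "SummarizedExperiment",
    slots = c(valueKind = "character"),
    prototype = prototype(valueKind = "raw")
)

setValidity("AtlasExperiment", function(object) {
    msg <- character()
    if (length(object@valueKind) != 1L ||
        !object@valueKind %in% c("raw", "percentile"))
        msg <- c(msg, "valueKind must be one of 'raw', 'percentile'")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene (row) and sample (column) names are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (identical(object@valueKind, "percentile") && nrow(object) &&
        ncol(object)) {
        v <- assay(object, withDimnames = FALSE)
        rng <- range(as.numeric(v))
        if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
            msg <- c(msg, "percentile values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AtlasExperiment
#'
#' @param values numeric gene-by-sample matrix (dense or sparse `Matrix`)
#'   with gene ids as row names and sample ids as column names.
#' @param annotation optional per-sample annotation: a `data.frame` or
#'   `DataFrame` with a `sample_id` column (or row names) matching the
#'   columns of `values`. See [readAnnotation()] for the expected columns.
#' @param valueKind `"raw"` (default) or `"percentile"`.
#'
#' @return An [AtlasExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ae <- AtlasExperiment(m)
#' valueKind(ae)
#' @export
AtlasExperiment <- function(values, annotation = NULL, valueKind = "raw") {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have gene row names and sample column names")
    cd <- DataFrame(row.names = colnames(values))
    if (!is.null(annotation)) {
        annotation <- .asAnnotation(annotation)
        miss <- setdiff(colnames(values), rownames(annotation))
        if (length(miss))
            stop("samples absent from annotation: ",
                 paste(utils::head(miss, 5), collapse = ", "))
        cd <- annotation[colnames(values), , drop = FALSE]
    }
    se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
    new("AtlasExperiment", se, valueKind = valueKind)
}

# coerce an annotation table to a DataFrame keyed by sample_id row names
.asAnnotation <- function(annotation) {
    annotation <- as(annotation, "DataFrame")
    if ("sample_id" %in% colnames(annotation)) {
        if (anyDuplicated(annotation$sample_id))
            stop("duplicate sample_id in annotation")
        rownames(annotation) <- annotation$sample_id
    } else if (is.null(rownames(annotation))) {
        stop("annotation needs a 'sample_id' column or row names")
    }
    annotation
}

#' AtlasModel: a fitted PCA reference atlas
#'
#' Stores everything needed to reproduce and reuse a fitted atlas: the
#' platform-robust gene subset, per-gene training mean percentiles, the
#' orthonormal principal-axis loadings, per-component explained variances,
#' the training-sample coordinates, and the build parameters.
#'
#' The loadings matrix is components x genes with unit-norm rows; each row's
#' sign is fixed so that its largest-magnitude entry is positive, making
#' coordinates reproducible across runs and linear-algebra backends.
#'
#' @slot selectedGenes character, ordered gene ids entering the PCA.
#' @slot geneMeans numeric, mean training percentile per selected gene.
#' @slot loadings numeric matrix, components x genes.
#' @slot explainedVariance numeric, non-increasing, one entry per component.
#' @slot trainingCoords numeric matrix, samples x components.
#' @slot threshold numeric in (0, 1], the platform-variance-fraction cutoff.
#' @slot nComponents integer, number of retained components.
#' @slot provenance list of build parameters (threshold, seed, sample and
#'   platform counts, package version).
#' @export
setClass("AtlasModel",
    slots = c(
        selectedGenes = "character",
        geneMeans = "numeric",
        loadings = "matrix",
        explainedVariance = "numeric",
        trainingCoords = "matrix",
        threshold = "numeric",
        nComponents = "integer",
        provenance = "list"
    )
)

setValidity("AtlasModel", function(object) {
    msg <- character()
    G <- length(object@selectedGenes)
    k <- object@nComponents
    if (anyDuplicated(object@selectedGenes))
        msg <- c(msg, "duplicate selected genes")
    if (length(object@geneMeans) != G)
        msg <- c(msg, "geneMeans length must match selectedGenes")
    if (!identical(dim(object@loadings), c(as.integer(k), as.integer(G))))
        msg <- c(msg, "loadings must be nComponents x nGenes")
    if (length(object@explainedVariance) != k)
        msg <- c(msg, "explainedVariance length must equal nComponents")
    else if (k > 1 && any(diff(object@explainedVariance) > 1e-8))
        msg <- c(msg, "explainedVariance must be non-increasing")
    if (ncol(object@trainingCoords) != k)
        msg <- c(msg, "trainingCoords must have nComponents columns")
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold > 1)
        msg <- c(msg, "threshold must lie in (0, 1]")
    if (G && k) {
        rn <- sqrt(rowSums(object@loadings^2))
        if (any(abs(rn - 1) > 1e-6))
            msg <- c(msg, "loading rows must be unit norm")
    }
    if (length(msg)) msg else TRUE
})

#' StabilityReport: resampling stability of a clustering
#'
#' Summarises, for one (algorithm, scheme, k) combination, the per-cluster
#' Jaccard H-indices obtained by re-running the complete atlas pipeline on
#' resampled data, plus the stability of the selected gene set.
#'
#' @slot algorithm `"kmeans"` or `"agglomerative"`.
#' @slot scheme `"jackknife"` (leave-one-dataset-out) or `"bootstrap"`.
#' @slot k integer, number of clusters.
#' @slot perClusterH numeric in \[0, 1\], one H-index per original cluster.
#' @slot nResamples integer, resamples actually evaluated.
#' @slot nSkipped integer, resamples skipped (fewer than 2 platforms or too
#'   few selected genes).
#' @slot geneOverlapPct numeric, per-resample percentage of the full-data
#'   selected genes recovered in the resample's selection.
#' @export
setClass("StabilityReport",
    slots = c(
        algorithm = "character",
        scheme = "character",
        k = "integer",
        perClusterH = "numeric",
        nResamples = "integer",
        nSkipped = "integer",
        geneOverlapPct = "numeric"
    )
)

setValidity("StabilityReport", function(object) {
    msg <- character()
    if (!object@algorithm %in% c("kmeans", "agglomerative"))
        msg <- c(msg, "algorithm must be 'kmeans' or 'agglomerative'")
    if (!object@scheme %in% c("jackknife", "bootstrap"))
        msg <- c(msg, "scheme must be 'jackknife' or 'bootstrap'")
    if (length(object@perClusterH) &&
        (min(object@perClusterH) < 0 || max(object@perClusterH) > 1))
        msg <- c(msg, "per-cluster H must lie in [0, 1]")
    if (length(object@geneOverlapPct) &&
        (min(object@geneOverlapPct) < 0 || max(object@geneOverlapPct) > 100))
        msg <- c(msg, "gene overlap percentages must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})
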