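#' Genes measurable on every platform
#'
#' Atlas construction only uses genes present on all contributing
#' platforms. Given one or more expression matrices and the platform each
#' came from, returns the intersection of the platform-wise gene sets in
#' sorted order.
#'
#' @param matrices list of [AtlasExperiment-class] (or matrices with gene
#'   row names).
#' @param platformOf character vector, platform of each matrix (recycled if
#'   length 1). Gene sets of matrices sharing a platform are unioned before
#'   intersecting across platforms.
#' @return sorted character vector of common gene ids.
#' @export
commonGeneUniverse <- function(matrices, platformOf) {
    if (!length(matrices)) stop("no matrices supplied")
    platformOf <- rep_len(as.character(platformOf), length(matrices))
    geneSets <- lapply(split(matrices, platformOf), function(ms)
        unique(unlist(lapply(ms, rownames))))
    common <- Reduce(intersect, geneSets)
    if (!length(common))
        stop("no genes are shared across all platforms")
    sort(common)
}

#' Select genes below the platform-variance threshold
#'
#' @param genevar data.frame from [platformVarianceFraction()].
#' @param threshold fraction cutoff in (0, 1]; genes with
#'   `fraction_platform` strictly below it are kept (boundary genes are
#'   excluded), in their original order.
#' @return character vector of gene ids.
#' @export
selectGenes <- function(genevar, threshold = 0.2) {
    if (length(threshold) != 1 || threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    keep <- genevar$gene_id[genevar$fraction_platform < threshold]
    if (!length(keep))
        stop("no genes pass the platform-variance threshold ", threshold,
            "; try a larger threshold")
    keep
}

#' Atlas build parameters
#'
#' @param threshold platform-variance-fraction cutoff in (0, 1]; genes
#'   strictly below it enter the PCA. Default 0.2.
#' @param nComponents principal components to retain (the first 3 are the
#'   display space; 10 supports the platform-dependence diagnostics).
#' @param seed integer recorded in provenance (the fit itself is
#'   deterministic).
#' @return list of class `buildConfig`.
#' @export
buildConfig <- function(threshold = 0.2, nComponents = 10, seed = 0) {
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    if (nComponents < 1) stop("nComponents must be >= 1")
    structure(list(threshold = threshold,
        nComponents = as.integer(nComponents), seed = as.integer(seed)),
        class = "buildConfig")
}

#' Fit a PCA atlas on platform-robust genes
#'
#' The build pipeline: per-gene platform variance fractions
#' ([platformVarianceFraction()]) on the percentile data, gene selection
#' strictly below `threshold` ([selectGenes()]), centering of each selected
#' gene on its training mean (no variance scaling), and PCA of the
#' centred samples-by-genes matrix. Loadings are stored components x genes
#' with each component's sign fixed so its largest-magnitude loading is
#' positive.
#'
#' @param x an [AtlasExperiment-class] with percentile values (see
#'   [rankPercentile()]); `colData` (or `annotation`) must provide
#'   `platform` for every sample.
#' @param config a [buildConfig()].
#' @param annotation optional annotation override.
#' @return An [AtlasModel-class].
#' @export
fitAtlas <- function(x, config = buildConfig(), annotation = NULL) {
    if (is(x, "AtlasExperiment") && !identical(valueKind(x), "percentile"))
        stop("fitAtlas expects rank-percentile values; run rankPercentile()")
    v <- .alignedValues(x, annotation)
    genevar <- platformVarianceFraction(x, annotation)
    genes <- selectGenes(genevar, config$threshold)
    .fitPca(v$values, genes, config, nPlatforms = length(unique(v$platform)))
}

.fitPca <- function(m, genes, config, nPlatforms) {
    sub <- t(m[genes, , drop = FALSE])       # samples x genes
    k <- config$nComponents
    if (nrow(sub) < k)
        stop("fewer samples (", nrow(sub), ") than components (", k, ")")
    if (length(genes) < k)
        stop("fewer selected genes (", length(genes), ") than components")
    pca <- stats::prcomp(sub, center = TRUE, scale. = FALSE, rank. = k)
    kAvail <- ncol(pca$rotation)
    if (kAvail < k)
        stop("only ", kAvail, " components available; lower nComponents")
    loadings <- t(pca$rotation[, seq_len(k), drop = FALSE])  # k x genes
    coords <- pca$x[, seq_len(k), drop = FALSE]
    # sign convention: largest-magnitude loading of each component positive
    flip <- apply(loadings, 1, function(r) sign(r[which.max(abs(r))]))
    flip[flip == 0] <- 1
    loadings <- loadings * flip
    coords <- sweep(coords, 2, flip, `*`)
    colnames(coords) <- paste0("PC", seq_len(k))
    rownames(loadings) <- NULL
    new("AtlasModel",
        selectedGenes = genes,
        geneMeans = pca$center,
        loadings = loadings,
        explainedVariance = pca$sdev[seq_len(k)]^2,
        trainingCoords = coords,
        threshold = config$threshold,
        nComponents = as.integer(k),
        provenance = list(
            seed = config$seed,
            n_samples = nrow(sub),
            n_platforms = nPlatforms,
            n_genes_in = ncol(m),
            package = as.character(utils::packageVersion("rankatlas"))))
}

#' Recursive atlas refinement on a sample subset
#'
#' Re-runs the complete build — variance partitioning, gene selection and
#' PCA — from scratch on a subset of the training samples. Selection is
#' subset-specific, so parent and child atlases generally use different
#' gene lists; this is what lets a sub-atlas resolve finer cell-type
#' structure than the parent coordinates.
#'
#' @param x the parent [AtlasExperiment-class] (percentile values).
#' @param sampleSubset character vector of sample ids to keep; must span at
#'   least 2 platforms.
#' @param config a [buildConfig()].
#' @param annotation optional annotation override.
#' @return An [AtlasModel-class] fitted on the subset.
#' @export
buildSubatlas <- function(x, sampleSubset, config = buildConfig(),
                          annotation = NULL) {
    if (!length(sampleSubset)) stop("empty sample subset")
    miss <- setdiff(sampleSubset, colnames(x))
    if (length(miss))
        stop("subset samples not in the data: ",
            paste(utils::head(miss, 5), collapse = ", "))
    sub <- x[, sampleSubset]
    ann <- if (is.null(annotation)) NULL else
        .asAnnotation(annotation)[sampleSubset, , drop = FALSE]
    fitAtlas(sub, config, ann)
}

#' Platform dependence of atlas components
#'
#' For each of the first `nComponents` components, the Kruskal-Wallis H
#' statistic of the training coordinates grouped by platform. Low H means
#' platform has little effect on the component; the statistic shrinks as
#' the gene-selection threshold is tightened.
#'
#' @param model an [AtlasModel-class].
#' @param annotation annotation covering the training samples (`platform`
#'   column). Platforms with fewer than 2 training samples are dropped with
#'   a warning.
#' @param nComponents how many leading components to test (default up to
#'   10).
#' @return data.frame with `component`, `kw_h_statistic`, `n_platforms`.
#' @export
componentPlatformDependence <- function(model, annotation,
                                        nComponents = 10) {
    nComponents <- min(nComponents, model@nComponents)
    coords <- model@trainingCoords
    ann <- .asAnnotation(annotation)
    miss <- setdiff(rownames(coords), rownames(ann))
    if (length(miss))
        stop("training samples without annotation: ",
            paste(utils::head(miss, 5), collapse = ", "))
    platform <- as.character(ann[rownames(coords), "platform"])
    tooSmall <- names(which(table(platform) < 2))
    if (length(tooSmall)) {
        warning("dropping platform(s) with < 2 samples: ",
            paste(tooSmall, collapse = ", "))
        keep <- !platform %in% tooSmall
        coords <- coords[keep, , drop = FALSE]
        platform <- platform[keep]
    }
    g <- factor(platform)
    if (nlevels(g) < 2) stop("need at least 2 platforms with >= 2 samples")
    h <- vapply(seq_len(nComponents), function(j) {
        sc <- coords[, j]
        if (length(unique(sc)) == 1) return(0)  # all tied: no rank variation
        unname(stats::kruskal.test(sc, g)$statistic)
    }, numeric(1))
    data.frame(component = seq_len(nComponents), kw_h_statistic = h,
        n_platforms = nlevels(g))
}
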