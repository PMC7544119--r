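#' Project external samples onto a fitted atlas
#'
#' Each new sample is rank-percentile transformed over its own full
#' measured gene set, restricted to the atlas's selected genes, centred by
#' the stored training gene means and multiplied by the stored loadings —
#' a purely linear map; the atlas is never refitted. Atlas genes missing
#' from the new data are given the lowest rank (percentile 0). A warning
#' is raised when more than half the atlas genes are missing, since a
#' large missing fraction distorts the projection.
#'
#' @param atlas an [AtlasModel-class].
#' @param x an [AtlasExperiment-class] (or gene-by-sample matrix) of raw
#'   expression; percentile input is used as-is.
#' @param flagQuantile quantile of the training nearest-neighbour distance
#'   distribution used as the off-atlas cutoff (see [offAtlasScore()]).
#' @return data.frame with one row per sample: `sample_id`, `PC1..PCk`,
#'   `n_missing_genes`, `missing_fraction`, `off_atlas_score`,
#'   `off_atlas_flag`.
#' @export
projectSamples <- function(atlas, x, flagQuantile = 0.95) {
    m <- if (is(x, "AtlasExperiment")) {
        if (identical(valueKind(x), "percentile")) as.matrix(exprValues(x))
        else rankPercentile(as.matrix(exprValues(x)))
    } else rankPercentile(as.matrix(x))
    genes <- selectedGenes(atlas)
    present <- intersect(genes, rownames(m))
    if (!length(present))
        stop("no overlap between the data's genes and the atlas genes")
    nMissing <- length(genes) - length(present)
    # selected genes x samples, absent genes at the lowest rank (0)
    p <- matrix(0, length(genes), ncol(m),
        dimnames = list(genes, colnames(m)))
    p[present, ] <- m[present, , drop = FALSE]
    missingFraction <- nMissing / length(genes)
    if (missingFraction > 0.5)
        warning(sprintf(paste0("%.0f%% of atlas genes are missing from the",
            " projected data; the projection will be distorted"),
            100 * missingFraction))
    centred <- p - geneMeans(atlas)[genes]
    coords <- t(centred) %*% t(atlasLoadings(atlas))
    colnames(coords) <- paste0("PC", seq_len(atlas@nComponents))
    score <- offAtlasScore(atlas, coords, flagQuantile)
    out <- data.frame(sample_id = colnames(m), coords,
        n_missing_genes = nMissing, missing_fraction = missingFraction,
        off_atlas_score = score$score, off_atlas_flag = score$flag,
        row.names = NULL, stringsAsFactors = FALSE)
    out
}

#' Distance-based off-atlas caution score
#'
#' A projected sample that lands far from every populated region of the
#' atlas is transcriptionally unlike all training samples and its
#' coordinates should not be over-interpreted. The score is the Euclidean
#' distance, in the first 3 components (the display space), to the nearest
#' training sample; the flag is raised when the score exceeds the
#' `flagQuantile` quantile of the training samples' own nearest-neighbour
#' distances.
#'
#' @param atlas an [AtlasModel-class].
#' @param coords samples x components matrix of projected coordinates (at
#'   least 3 columns, as produced by [projectSamples()]).
#' @param flagQuantile quantile defining the cutoff (default 0.95).
#' @return list with numeric `score`, logical `flag` and the numeric
#'   `cutoff` used.
#' @export
offAtlasScore <- function(atlas, coords, flagQuantile = 0.95) {
    d <- min(3L, atlas@nComponents)
    train <- trainingCoords(atlas)[, seq_len(d), drop = FALSE]
    q <- as.matrix(coords)[, seq_len(d), drop = FALSE]
    # nearest-neighbour distances of training points to each other
    dt <- as.matrix(stats::dist(train))
    diag(dt) <- Inf
    nnTrain <- apply(dt, 1, min)
    cutoff <- stats::quantile(nnTrain, flagQuantile, names = FALSE)
    cross <- outer(rowSums(q^2), rep(1, nrow(train))) +
        outer(rep(1, nrow(q)), rowSums(train^2)) -
        2 * q %*% t(train)
    score <- sqrt(pmax(apply(cross, 1, min), 0))
    list(score = unname(score), flag = unname(score > cutoff),
        cutoff = cutoff)
}

#' Pseudo-bulk aggregation of single cells
#'
#' Within each cluster, cells are randomly partitioned (under the seed)
#' into pools of exactly `poolSize` cells and each pool's counts are
#' summed gene-wise into one pseudo-bulk sample. Pools inherit the cluster
#' identity. With `dropRemainder` (the default) leftover cells are
#' discarded so every pool has the same number of cells; clusters smaller
#' than `poolSize` yield no pools (with a warning).
#'
#' @param cells an [AtlasExperiment-class] (or gene-by-cell matrix, dense
#'   or sparse) of non-negative counts.
#' @param clusterLabels per-cell cluster identity: named vector, or
#'   unnamed in the cell order of `cells`.
#' @param poolSize cells per pool (default 9; 8-10 cells per aggregate
#'   approximates bulk data structure for 10x data).
#' @param dropRemainder drop cells that do not fill a complete pool.
#' @param seed integer seed for the random partition.
#' @return list with `pools`, an [AtlasExperiment-class] of summed counts
#'   (`valueKind = "raw"`), and `annotation`, a data.frame (`sample_id`,
#'   `cluster`, `n_cells`).
#' @export
pseudobulk <- function(cells, clusterLabels, poolSize = 9,
                       dropRemainder = TRUE, seed = 0) {
    m <- if (is(cells, "AtlasExperiment")) exprValues(cells) else cells
    if (poolSize < 1) stop("poolSize must be >= 1")
    if (min(m) < 0) stop("counts must be non-negative")
    if (is.null(names(clusterLabels))) {
        if (length(clusterLabels) != ncol(m))
            stop("clusterLabels length does not match the number of cells")
        names(clusterLabels) <- colnames(m)
    }
    miss <- setdiff(colnames(m), names(clusterLabels))
    if (length(miss))
        stop("unlabelled cells: ", paste(utils::head(miss, 5),
            collapse = ", "))
    clusterLabels <- clusterLabels[colnames(m)]
    pools <- list(); ann <- list()
    .withSeed(seed, {
        for (cl in unique(as.character(clusterLabels))) {
            ids <- colnames(m)[clusterLabels == cl]
            nPools <- length(ids) %/% poolSize
            if (nPools == 0) {
                warning("cluster '", cl, "' has fewer cells (", length(ids),
                    ") than poolSize; no pools emitted")
                next
            }
            ids <- sample(ids)
            if (!dropRemainder && length(ids) %% poolSize)
                nPools <- nPools + 1L
            for (i in seq_len(nPools)) {
                member <- ids[(poolSize * (i - 1) + 1):
                    min(poolSize * i, length(ids))]
                nm <- sprintf("%s_pool%02d", cl, i)
                pools[[nm]] <- Matrix::rowSums(
                    m[, member, drop = FALSE])
                ann[[nm]] <- data.frame(sample_id = nm, cluster = cl,
                    n_cells = length(member), stringsAsFactors = FALSE)
            }
        }
    })
    if (!length(pools)) stop("no pools could be formed")
    pm <- do.call(cbind, pools)
    rownames(pm) <- rownames(m)
    annotation <- do.call(rbind, c(ann, list(make.row.names = FALSE)))
    list(pools = AtlasExperiment(pm, valueKind = "raw"),
        annotation = annotation)
}
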