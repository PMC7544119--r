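# evaluate expr under set.seed(seed), restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Cluster atlas coordinates
#'
#' K-means (with multiple random restarts under the seed) or agglomerative
#' hierarchical clustering with Euclidean distance and Ward linkage
#' (`hclust` method `"ward.D2"`, the Ward criterion on Euclidean
#' distances). By default the first 3 components — the display space of the
#' atlas — are used.
#'
#' @param coords samples x components numeric matrix (e.g.
#'   [trainingCoords()] or projected coordinates) with sample ids as row
#'   names.
#' @param k number of clusters, `2 <= k <= nrow(coords)`.
#' @param algorithm `"kmeans"` or `"agglomerative"`.
#' @param dims how many leading components to cluster on (default
#'   `min(3, ncol)`).
#' @param seed integer seed for the k-means restarts (agglomerative is
#'   deterministic).
#' @param nstart k-means restarts.
#' @return named integer vector of cluster labels in `1..k`, one per
#'   sample.
#' @export
clusterCoords <- function(coords, k, algorithm = c("kmeans",
        "agglomerative"), dims = NULL, seed = 0, nstart = 25) {
    algorithm <- match.arg(algorithm)
    coords <- as.matrix(coords)
    if (is.null(dims)) dims <- min(3L, ncol(coords))
    if (k > nrow(coords))
        stop("k (", k, ") exceeds the number of samples (", nrow(coords), ")")
    if (k < 1) stop("k must be >= 1")
    m <- coords[, seq_len(dims), drop = FALSE]
    labels <- if (k == nrow(m)) {
        seq_len(k)                       # every sample its own cluster
    } else if (algorithm == "kmeans") {
        .withSeed(seed,
            stats::kmeans(m, centers = k, nstart = nstart,
                iter.max = 100)$cluster)
    } else {
        stats::cutree(stats::hclust(stats::dist(m), method = "ward.D2"), k)
    }
    stats::setNames(as.integer(labels), rownames(coords))
}

#' Jaccard similarity of two sample sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty.
#'
#' @param a,b character vectors of sample ids (treated as sets).
#' @return numeric in \[0, 1\].
#' @examples
#' jaccardIndex(c("s1", "s2", "s3"), c("s2", "s3", "s4"))  # 0.5
#' @export
jaccardIndex <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(union(a, b))
    if (u == 0) return(0)
    length(intersect(a, b)) / u
}

#' Continuous H-index of a Jaccard profile
#'
#' Summarises a cluster's maximum-Jaccard matches `J_1..J_B` over B
#' resamples as the largest h in \[0, 1\] such that a fraction at least h
#' of the resamples achieved Jaccard at least h. Equals 1 exactly when the
#' cluster is recovered perfectly in every resample, and is invariant to
#' the order of the resamples.
#'
#' @param jaccards numeric vector of per-resample maximum Jaccard values.
#' @return numeric in \[0, 1\].
#' @examples
#' hIndex(c(1, 1, 1, 1))        # 1
#' hIndex(rep(0.9, 10))         # 0.9
#' hIndex(c(1, 1, 0, 0))        # 0.5
#' @export
hIndex <- function(jaccards) {
    B <- length(jaccards)
    if (!B) stop("empty Jaccard profile")
    if (any(jaccards < 0 | jaccards > 1)) stop("Jaccard values outside [0,1]")
    js <- sort(jaccards, decreasing = TRUE)
    max(pmin(js, seq_len(B) / B))
}

#' Cluster stability under resampling of the full pipeline
#'
#' For each k, the data are clustered once in full ([fitAtlas()] then
#' [clusterCoords()]); then, for every resample — leave-one-dataset-out
#' jackknife or bootstrap of samples (or datasets) with replacement — the
#' *entire* pipeline (platform variance partition, gene selection, PCA,
#' clustering) is re-run on the resampled sample set. Each original
#' cluster is matched to the resample clustering by its maximum Jaccard
#' similarity over the shared samples, and the per-resample maxima are
#' summarised by the continuous [hIndex()]. The stability of the gene
#' selection itself is tracked as the percentage of full-data selected
#' genes recovered in each resample.
#'
#' Resamples spanning fewer than 2 platforms, or whose gene selection
#' returns fewer genes than the PCA needs, are skipped and counted.
#' Bootstrap duplicates are collapsed to unique sample ids before Jaccard
#' computation.
#'
#' @param x an [AtlasExperiment-class] with percentile values and
#'   annotation (`platform`, `dataset_id`).
#' @param config a [buildConfig()].
#' @param kValues integers, the cluster numbers to assess (default 2..10).
#' @param algorithm `"kmeans"` or `"agglomerative"`.
#' @param scheme `"bootstrap"` or `"jackknife"` (leave-one-dataset-out;
#'   needs >= 3 datasets).
#' @param nBoot bootstrap resamples (the jackknife count is the number of
#'   datasets).
#' @param unit bootstrap resampling unit, `"sample"` or `"dataset"`.
#' @param dims components to cluster on (default 3).
#' @param seed integer seed driving resampling and k-means restarts.
#' @param annotation optional annotation override.
#' @return list of [StabilityReport-class], one per k (named by k).
#' @export
resampleStability <- function(x, config = buildConfig(), kValues = 2:10,
        algorithm = c("kmeans", "agglomerative"),
        scheme = c("bootstrap", "jackknife"), nBoot = 500,
        unit = c("sample", "dataset"), dims = 3, seed = 0,
        annotation = NULL) {
    algorithm <- match.arg(algorithm)
    scheme <- match.arg(scheme)
    unit <- match.arg(unit)
    v <- .alignedValues(x, annotation,
        fields = c("platform", "dataset_id"))
    m <- v$values
    platform <- stats::setNames(v$platform, colnames(m))
    dataset <- stats::setNames(v$dataset_id, colnames(m))
    samples <- colnames(m)

    full <- .pipelineCluster(m, platform, config, kValues, algorithm,
        dims, seed)
    if (is.null(full))
        stop("full-data gene selection returned too few genes")

    # resampled sample-id multisets
    resampleIds <- if (scheme == "jackknife") {
        ds <- unique(dataset)
        if (length(ds) < 3)
            stop("jackknife needs at least 3 datasets")
        lapply(ds, function(d) samples[dataset != d])
    } else {
        if (nBoot < 1) stop("nBoot must be >= 1")
        .withSeed(seed, lapply(seq_len(nBoot), function(b) {
            if (unit == "sample")
                sample(samples, length(samples), replace = TRUE)
            else {
                ds <- unique(dataset)
                picked <- sample(ds, length(ds), replace = TRUE)
                unlist(lapply(picked, function(d) samples[dataset == d]))
            }
        }))
    }

    B <- length(resampleIds)
    # per resample and k: max Jaccard per original cluster; plus overlap
    perK <- lapply(kValues, function(k)
        vector("list", B))
    names(perK) <- as.character(kValues)
    overlap <- rep(NA_real_, B)
    skipped <- 0L
    for (b in seq_len(B)) {
        ids <- unique(resampleIds[[b]])
        if (length(unique(platform[ids])) < 2) { skipped <- skipped + 1L
            next }
        res <- .pipelineCluster(m[, ids, drop = FALSE], platform[ids],
            config, kValues, algorithm, dims, seed + b)
        if (is.null(res)) { skipped <- skipped + 1L; next }
        overlap[b] <- 100 *
            length(intersect(res$genes, full$genes)) / length(full$genes)
        for (k in as.character(kValues)) {
            lab <- res$labels[[k]]
            orig <- full$labels[[k]]
            shared <- intersect(names(orig), names(lab))
            perK[[k]][[b]] <- vapply(seq_len(as.integer(k)), function(cl) {
                a <- intersect(names(orig)[orig == cl], shared)
                if (!length(a)) return(NA_real_)
                max(vapply(unique(lab[shared]), function(cl2)
                    jaccardIndex(a,
                        intersect(names(lab)[lab == cl2], shared)),
                    numeric(1)))
            }, numeric(1))
        }
    }
    used <- B - skipped
    if (!used) stop("all resamples were skipped")
    lapply(stats::setNames(as.character(kValues), as.character(kValues)),
        function(k) {
        jmat <- do.call(rbind, Filter(Negate(is.null), perK[[k]]))
        perCluster <- apply(jmat, 2, function(col) {
            col <- col[!is.na(col)]
            # a cluster never observed in any resample is maximally unstable
            if (!length(col)) 0 else hIndex(col)
        })
        new("StabilityReport",
            algorithm = algorithm, scheme = scheme, k = as.integer(k),
            perClusterH = unname(perCluster),
            nResamples = as.integer(used), nSkipped = skipped,
            geneOverlapPct = overlap[!is.na(overlap)])
    })
}

# run variance partition -> selection -> PCA -> clustering at each k;
# NULL when the selection cannot support the PCA
.pipelineCluster <- function(m, platform, config, kValues, algorithm,
                             dims, seed) {
    ann <- DataFrame(sample_id = colnames(m), dataset_id = "x",
        platform = platform, row.names = colnames(m))
    genevar <- suppressWarnings(platformVarianceFraction(m, ann))
    genes <- tryCatch(selectGenes(genevar, config$threshold),
        error = function(e) character())
    cfg <- config
    cfg$nComponents <- min(config$nComponents, ncol(m) - 1L)
    if (length(genes) < max(cfg$nComponents, dims) ||
        ncol(m) <= max(cfg$nComponents, dims))
        return(NULL)
    model <- .fitPca(m, genes, cfg, length(unique(platform)))
    labels <- lapply(stats::setNames(kValues, as.character(kValues)),
        function(k) clusterCoords(trainingCoords(model), k, algorithm,
            dims = min(dims, cfg$nComponents), seed = seed))
    list(genes = genes, labels = labels)
}

#' Choose k from a stability profile
#'
#' The optimal cluster number is the k immediately before the first strict
#' decrease of the median H-index along the ascending k grid; if the
#' medians never decrease, the largest k is returned with a warning.
#'
#' @param reports list of [StabilityReport-class] ordered by ascending k
#'   (as from [resampleStability()]).
#' @return integer, the chosen k.
#' @examples
#' # medians 0.90, 0.92, 0.85 over k = 2..4 select k = 3
#' @export
selectK <- function(reports) {
    if (!length(reports)) stop("no stability reports")
    ks <- vapply(reports, function(r) r@k, integer(1))
    reports <- reports[order(ks)]
    ks <- sort(ks)
    med <- vapply(reports, medianH, numeric(1))
    if (length(med) > 1)
        for (i in seq_len(length(med) - 1))
            if (med[i + 1] < med[i]) return(ks[i])
    warning("median H-index never decreased over the k grid; ",
        "returning the largest k")
    ks[length(ks)]
}
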