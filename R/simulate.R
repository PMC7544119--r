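#' Simulation parameters for multi-platform expression data
#'
#' Defaults emulate a small multi-platform compendium: 10 cell types
#' profiled on 4 platforms (2 microarray-like, 2 RNA-seq-like), 2 datasets
#' per platform and 5 samples per dataset per cell type — 400 samples in
#' all — with half the genes carrying platform-specific distortions.
#'
#' @param nGenes number of genes.
#' @param nCelltypes number of cell types.
#' @param platforms data.frame with columns `name`, `kind`
#'   (`"microarray"`/`"rnaseq"`) and `distortion_strength` (>= 0, in log2
#'   units); default 4 platforms, distortion 1.
#' @param nDatasetsPerPlatform independent datasets per platform.
#' @param samplesPerDatasetPerCelltype replicates per (dataset, cell
#'   type).
#' @param fracPlatformAffected fraction of genes receiving
#'   platform-specific distortions.
#' @param fracMarkerPerCelltype fraction of genes that are markers of each
#'   cell type.
#' @param effectSizeLog2 log2 up-shift of a marker gene in its cell type.
#' @param noiseSd residual log2 noise standard deviation.
#' @param datasetSd standard deviation of small per-(gene, dataset)
#'   offsets modelling residual batch structure.
#' @param arrayFloor additive microarray background intensity (keeps
#'   microarray values continuous and strictly positive).
#' @param nbSize negative-binomial dispersion (size) for RNA-seq counts.
#' @param dropoutRate extra probability that an RNA-seq count is zeroed.
#' @param distortionProfile `"heterogeneous"` (default) draws a
#'   gene-specific distortion scale from Exp(mean = 1) so that platform
#'   effects vary continuously across affected genes, as in real
#'   compendia; `"uniform"` gives every affected gene the same scale 1.
#'   Platform `distortion_strength` multiplies the scale either way.
#' @param seed integer seed; the output is bit-identical for equal seeds.
#' @return list of class `simConfig`.
#' @export
simConfig <- function(nGenes = 2000, nCelltypes = 10,
        platforms = data.frame(
            name = c("array_A", "array_B", "rnaseq_A", "rnaseq_B"),
            kind = c("microarray", "microarray", "rnaseq", "rnaseq"),
            distortion_strength = 1,
            stringsAsFactors = FALSE),
        nDatasetsPerPlatform = 2, samplesPerDatasetPerCelltype = 5,
        fracPlatformAffected = 0.5, fracMarkerPerCelltype = 0.025,
        effectSizeLog2 = 3, noiseSd = 1, datasetSd = 0.25,
        arrayFloor = 32, nbSize = 10, dropoutRate = 0.05,
        distortionProfile = c("heterogeneous", "uniform"), seed = 1) {
    distortionProfile <- match.arg(distortionProfile)
    stopifnot(nGenes >= 2, nCelltypes >= 1,
        all(platforms$kind %in% c("microarray", "rnaseq")),
        all(platforms$distortion_strength >= 0),
        fracPlatformAffected >= 0, fracPlatformAffected <= 1,
        fracMarkerPerCelltype >= 0, fracMarkerPerCelltype <= 1,
        dropoutRate >= 0, dropoutRate <= 1,
        nDatasetsPerPlatform >= 1, samplesPerDatasetPerCelltype >= 1)
    structure(as.list(environment()), class = "simConfig")
}

#' Simulate a multi-platform, multi-dataset expression compendium
#'
#' Generates the test bed for the atlas pipeline: several cell types
#' measured across microarray-like platforms (continuous intensities with
#' a non-zero background floor) and RNA-seq-like platforms (discrete
#' counts with exact zeros), with known gene-wise platform distortions and
#' cell-type marker structure.
#'
#' Per gene, a baseline log2 abundance is drawn from Normal(6, 2). Marker
#' genes are shifted up by `effectSizeLog2` in their cell type.
#' Platform-affected genes receive, per platform, an additive log2 shift
#' drawn from Normal(0, distortion) and a multiplicative slope from
#' Normal(1, 0.2 * distortion). Small per-(gene, dataset) offsets model
#' residual batch effects; i.i.d. Normal(0, noiseSd) log2 noise is added
#' per measurement. Microarray platforms emit
#' `2^(log2 signal) + arrayFloor` (strictly positive, no exact zeros);
#' RNA-seq platforms emit negative-binomial counts with mean
#' `2^(log2 signal)` and extra dropout zeros.
#'
#' @param config a [simConfig()].
#' @return list with `expression` (an [AtlasExperiment-class], raw,
#'   annotation in `colData`), `annotation` (a `DataFrame`), and `truth`
#'   (list: `gene_class` — `"neutral"`, `"marker"`, `"platform_affected"`
#'   or `"both"` per gene; `marker_of` — cell type a marker gene tags, NA
#'   otherwise; plus the per-sample `celltype`, `platform`, `dataset`
#'   vectors).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 200, nCelltypes = 3,
#'     samplesPerDatasetPerCelltype = 2, seed = 7))
#' sim$expression
#' @export
simulateExpression <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    c0 <- config
    .withSeed(c0$seed, {
        G <- c0$nGenes
        genes <- sprintf("gene%05d", seq_len(G))
        celltypes <- sprintf("celltype%02d", seq_len(c0$nCelltypes))
        base <- stats::rnorm(G, mean = 6, sd = 2)

        # gene roles: markers (per cell type, disjoint) and platform-affected
        nMarker <- round(c0$fracMarkerPerCelltype * G)
        markerOf <- rep(NA_character_, G)
        pool <- sample(G)
        taken <- 0
        for (ct in celltypes) {
            if (taken + nMarker > G) break
            markerOf[pool[taken + seq_len(nMarker)]] <- ct
            taken <- taken + nMarker
        }
        affected <- stats::runif(G) < c0$fracPlatformAffected
        geneClass <- ifelse(!is.na(markerOf),
            ifelse(affected, "both", "marker"),
            ifelse(affected, "platform_affected", "neutral"))

        # gene-specific distortion scale: platform effects are heterogeneous
        # across genes (most probes drift mildly, a few fail badly), giving
        # the continuous spread of platform-variance fractions seen in real
        # compendia; Exp(mean = distortion_strength) per affected gene
        P <- nrow(c0$platforms)
        dg <- rep(0, G)
        if (any(affected))
            dg[affected] <- if (c0$distortionProfile == "heterogeneous")
                stats::rexp(sum(affected), 1) else 1
        shift <- matrix(0, G, P)
        slope <- matrix(1, G, P)
        for (p in seq_len(P)) {
            d <- dg * c0$platforms$distortion_strength[p]
            shift[affected, p] <- stats::rnorm(sum(affected), 0, d[affected])
            slope[affected, p] <- stats::rnorm(sum(affected), 1,
                0.2 * d[affected])
        }

        cols <- list(); ann <- list()
        for (p in seq_len(P)) {
            pname <- c0$platforms$name[p]
            kind <- c0$platforms$kind[p]
            for (d in seq_len(c0$nDatasetsPerPlatform)) {
                dsname <- sprintf("%s_ds%d", pname, d)
                dsOffset <- stats::rnorm(G, 0, c0$datasetSd)
                for (ct in celltypes) {
                    for (r in seq_len(c0$samplesPerDatasetPerCelltype)) {
                        sid <- sprintf("%s_%s_r%d", dsname, ct, r)
                        mu <- base
                        isMk <- !is.na(markerOf) & markerOf == ct
                        mu[isMk] <- mu[isMk] + c0$effectSizeLog2
                        mu <- slope[, p] * mu + shift[, p] + dsOffset +
                            stats::rnorm(G, 0, c0$noiseSd)
                        cols[[sid]] <- if (kind == "microarray") {
                            2^mu + c0$arrayFloor
                        } else {
                            cnt <- stats::rnbinom(G, mu = 2^mu,
                                size = c0$nbSize)
                            cnt[stats::runif(G) < c0$dropoutRate] <- 0
                            cnt
                        }
                        ann[[sid]] <- data.frame(sample_id = sid,
                            dataset_id = dsname, platform = pname,
                            cell_type = ct, stringsAsFactors = FALSE)
                    }
                }
            }
        }
        m <- do.call(cbind, cols)
        rownames(m) <- genes
        annotation <- .asAnnotation(do.call(rbind,
            c(ann, list(make.row.names = FALSE))))
        expr <- AtlasExperiment(m, annotation, valueKind = "raw")
        list(expression = expr, annotation = annotation,
            truth = list(
                gene_class = stats::setNames(geneClass, genes),
                marker_of = stats::setNames(markerOf, genes),
                celltype = stats::setNames(annotation$cell_type,
                    annotation$sample_id),
                platform = stats::setNames(annotation$platform,
                    annotation$sample_id),
                dataset = stats::setNames(annotation$dataset_id,
                    annotation$sample_id)))
    })
}

#' Hold out one platform or dataset
#'
#' Splits a simulated compendium (or any annotated
#' [AtlasExperiment-class]) into disjoint train/test parts by platform or
#' dataset, for leave-one-platform-out projection experiments. The
#' training part must retain at least 2 platforms.
#'
#' @param x an [AtlasExperiment-class] with `platform` and `dataset_id`
#'   annotation.
#' @param unit `"platform"` or `"dataset"`.
#' @param held id of the unit to hold out.
#' @return list with `train` and `test` [AtlasExperiment-class] objects.
#' @export
heldoutSplit <- function(x, unit = c("platform", "dataset"), held) {
    unit <- match.arg(unit)
    col <- if (unit == "platform") "platform" else "dataset_id"
    ann <- colData(x)
    if (!col %in% colnames(ann)) stop("annotation lacks '", col, "'")
    vals <- as.character(ann[[col]])
    if (!held %in% vals) stop("no ", unit, " named '", held, "'")
    testIdx <- vals == held
    trainAnn <- ann[!testIdx, , drop = FALSE]
    if (length(unique(as.character(trainAnn$platform))) < 2)
        stop("holding out '", held, "' leaves fewer than 2 platforms")
    list(train = x[, !testIdx], test = x[, testIdx])
}
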