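test_that("the common gene universe is the cross-platform intersection", {
    m1 <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    m2 <- matrix(1, 3, 2, dimnames = list(c("b", "c", "d"), c("s3", "s4")))
    expect_identical(commonGeneUniverse(list(m1, m2), c("P1", "P2")),
        c("b", "c"))
    expect_identical(commonGeneUniverse(list(m1, m1), c("P1", "P2")),
        c("a", "b", "c"))
    # two matrices on the same platform contribute their union
    m3 <- matrix(1, 1, 1, dimnames = list("d", "s5"))
    expect_identical(
        commonGeneUniverse(list(m1, m3, m2), c("P1", "P1", "P2")),
        c("b", "c", "d"))
    m4 <- matrix(1, 2, 1, dimnames = list(c("x", "y"), "s6"))
    expect_error(commonGeneUniverse(list(m1, m4), c("P1", "P2")),
        "shared")
})

test_that("gene selection is strict-below-threshold and order preserving", {
    tab <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
        fraction_platform = c(0.1, 0.3, 0.19, 0.20))
    expect_identical(selectGenes(tab, 0.2), c("g1", "g3"))
    expect_identical(selectGenes(tab, 1.0), tab$gene_id)
    expect_error(selectGenes(tab, 0.05), "larger threshold")
    expect_error(selectGenes(tab, 1.5), "\\(0, 1\\]")
    # nested thresholds give nested selections
    set.seed(2)
    rt <- data.frame(gene_id = paste0("g", 1:200),
        fraction_platform = runif(200))
    for (pair in list(c(0.1, 0.5), c(0.3, 0.8), c(0.5, 1.0)))
        expect_true(all(selectGenes(rt, pair[1]) %in%
            selectGenes(rt, pair[2])))
})

test_that("fitted atlases reproduce their own training coordinates", {
    sim <- simulateExpression(simConfig(nGenes = 300, nCelltypes = 4,
        samplesPerDatasetPerCelltype = 2, seed = 5))
    pr <- rankPercentile(sim$expression)
    model <- fitAtlas(pr, buildConfig(threshold = 0.2, nComponents = 5))
    centred <- t(as.matrix(exprValues(pr))[selectedGenes(model), ]) -
        rep(geneMeans(model), each = ncol(pr))
    coords <- centred %*% t(atlasLoadings(model))
    expect_lt(max(abs(coords - trainingCoords(model))), 1e-10)
    # spectrum is non-increasing, loadings orthonormal
    expect_true(all(diff(explainedVariance(model)) <= 1e-8))
    L <- atlasLoadings(model)
    expect_lt(max(abs(L %*% t(L) - diag(5))), 1e-8)
    # identical input gives bit-identical output (fixed sign convention)
    model2 <- fitAtlas(pr, buildConfig(threshold = 0.2, nComponents = 5))
    expect_identical(trainingCoords(model), trainingCoords(model2))
    expect_identical(selectedGenes(model), selectedGenes(model2))
})

test_that("atlas building enforces its preconditions", {
    sim <- simulateExpression(simConfig(nGenes = 100, nCelltypes = 2,
        nDatasetsPerPlatform = 1, samplesPerDatasetPerCelltype = 1,
        seed = 6))
    pr <- rankPercentile(sim$expression)
    expect_error(fitAtlas(pr, buildConfig(nComponents = 50)),
        "fewer samples")
    expect_error(fitAtlas(sim$expression), "rank-percentile")
    expect_error(buildConfig(threshold = 0), "\\(0, 1\\]")
})

test_that("platform-affected genes are depleted among selected genes", {
    sim <- simulateExpression(simConfig(distortionProfile = "uniform",
        seed = 11))
    gv <- platformVarianceFraction(rankPercentile(sim$expression))
    sel <- selectGenes(gv, 0.2)
    gc <- sim$truth$gene_class
    affected <- names(gc)[gc %in% c("platform_affected", "both")]
    clean <- names(gc)[!gc %in% c("platform_affected", "both")]
    rateAff <- mean(affected %in% sel)
    rateClean <- mean(clean %in% sel)
    expect_gte(rateClean / rateAff, 5)
})

test_that("with no platform effect nearly all genes pass the 0.2 threshold", {
    pl <- data.frame(name = c("aA", "aB", "rA", "rB"),
        kind = c("microarray", "microarray", "rnaseq", "rnaseq"),
        distortion_strength = 0)
    sim <- simulateExpression(simConfig(platforms = pl,
        samplesPerDatasetPerCelltype = 3, seed = 5))
    gv <- platformVarianceFraction(rankPercentile(sim$expression))
    expect_gte(mean(gv$fraction_platform < 0.2), 0.95)
    expect_lte(median(gv$fraction_platform), 0.05)
})

test_that("sub-atlases re-run the full pipeline on the subset", {
    sim <- simulateExpression(simConfig(nGenes = 400, nCelltypes = 4,
        samplesPerDatasetPerCelltype = 2, seed = 9))
    pr <- rankPercentile(sim$expression)
    cfg <- buildConfig(threshold = 0.2, nComponents = 4)
    full <- fitAtlas(pr, cfg)
    same <- buildSubatlas(pr, colnames(pr), cfg)
    expect_identical(selectedGenes(same), selectedGenes(full))
    expect_equal(trainingCoords(same), trainingCoords(full))
    # a one-platform subset is unidentifiable
    onePlat <- colnames(pr)[sampleAnnotation(pr)$platform == "array_A"]
    expect_error(buildSubatlas(pr, onePlat, cfg), "unidentifiable")
    expect_error(buildSubatlas(pr, character(), cfg), "empty")
})

test_that("sub-atlas resolves subtypes better than parent coordinates", {
    # nested structure: cell types 1+2 and 3+4 form two coarse lineages by
    # adding a strong shared signature over a lineage gene set on top of
    # weak subtype markers; the parent display axes capture the lineage
    # split, the subatlas on one lineage resolves its two subtypes
    sim <- simulateExpression(simConfig(nGenes = 1000, nCelltypes = 4,
        effectSizeLog2 = 1.5, fracMarkerPerCelltype = 0.03, seed = 33))
    m <- as.matrix(exprValues(sim$expression))
    ct <- sim$truth$celltype[colnames(m)]
    set.seed(34)
    lineageGenes <- sample(rownames(m), 150)
    lineageA <- ct %in% c("celltype01", "celltype02")
    m[lineageGenes, lineageA] <- m[lineageGenes, lineageA] * 16
    ae <- AtlasExperiment(m, sim$annotation)
    pr <- rankPercentile(ae)
    cfg <- buildConfig(threshold = 0.2, nComponents = 5)
    parent <- fitAtlas(pr, cfg)
    subtypes <- c("celltype01", "celltype02")
    subset <- colnames(pr)[ct %in% subtypes]
    child <- buildSubatlas(pr, subset, cfg)
    silhouette <- function(coords, labels) {
        d <- as.matrix(dist(coords[, 1:3]))
        mean(vapply(seq_len(nrow(d)), function(i) {
            own <- mean(d[i, labels == labels[i] &
                seq_len(nrow(d)) != i])
            oth <- min(vapply(setdiff(unique(labels), labels[i]),
                function(l) mean(d[i, labels == l]), numeric(1)))
            (oth - own) / max(own, oth)
        }, numeric(1)))
    }
    labs <- unname(ct[subset])
    sParent <- silhouette(trainingCoords(parent)[subset, ], labs)
    sChild <- silhouette(trainingCoords(child), labs)
    expect_gt(sChild, sParent)
})

test_that("component platform dependence matches hand-computed Kruskal-Wallis", {
    # all scores tied across platforms: no rank variation, H = 0
    coords <- matrix(c(rep(1, 6), 1:6), ncol = 2,
        dimnames = list(paste0("s", 1:6), c("PC1", "PC2")))
    model <- new("AtlasModel", selectedGenes = paste0("g", 1:3),
        geneMeans = rep(0.5, 3), loadings = diag(3)[1:2, ],
        explainedVariance = c(2, 1), trainingCoords = coords,
        threshold = 0.2, nComponents = 2L, provenance = list())
    ann <- makeAnnotation(rownames(coords), rep(c("A", "B"), each = 3))
    res <- componentPlatformDependence(model, ann, nComponents = 2)
    expect_equal(res$kw_h_statistic[1], 0)
    # PC2 fully separates two platforms of 3: rank sums 6 and 15,
    # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 27/7
    expect_equal(res$kw_h_statistic[2], 27 / 7)
    # a platform with < 2 samples is dropped with a warning
    ann2 <- makeAnnotation(rownames(coords), c("A", "A", "A", "B", "B", "C"))
    expect_warning(componentPlatformDependence(model, ann2, 2), "dropping")
})
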