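trainTestAtlas <- function(seed = 31) {
    sim <- simulateExpression(simConfig(nGenes = 500, nCelltypes = 4,
        samplesPerDatasetPerCelltype = 2, effectSizeLog2 = 4,
        fracMarkerPerCelltype = 0.05, seed = seed))
    pr <- rankPercentile(sim$expression)
    model <- fitAtlas(pr, buildConfig(threshold = 0.2, nComponents = 5))
    list(sim = sim, pr = pr, model = model)
}

test_that("projecting the training samples reproduces their coordinates", {
    tt <- trainTestAtlas()
    proj <- projectSamples(tt$model, tt$sim$expression)
    got <- as.matrix(proj[, paste0("PC", 1:5)])
    expect_lt(max(abs(got - trainingCoords(tt$model))), 1e-10)
    expect_true(all(proj$n_missing_genes == 0))
    expect_true(all(proj$missing_fraction == 0))
})

test_that("missing atlas genes get the lowest rank and are counted", {
    tt <- trainTestAtlas()
    expr <- as.matrix(exprValues(tt$sim$expression))
    drop <- selectedGenes(tt$model)[1:10]
    masked <- expr[setdiff(rownames(expr), drop), , drop = FALSE]
    proj <- projectSamples(tt$model, masked)
    expect_true(all(proj$n_missing_genes == 10))
    expect_equal(proj$missing_fraction,
        rep(10 / length(selectedGenes(tt$model)), nrow(proj)))
    # masking more genes never decreases the missing count, and the
    # coordinate shift stays bounded by the loading norms
    drop2 <- selectedGenes(tt$model)[1:30]
    masked2 <- expr[setdiff(rownames(expr), drop2), , drop = FALSE]
    proj2 <- projectSamples(tt$model, masked2)
    expect_true(all(proj2$n_missing_genes >= proj$n_missing_genes))
    shift <- max(abs(as.matrix(proj2[, paste0("PC", 1:5)]) -
        as.matrix(proj[, paste0("PC", 1:5)])))
    expect_lt(shift, sqrt(20))  # 20 genes changed by at most 1 each

    # zero overlap is an error; heavy missingness warns
    alien <- matrix(1:4, 2, 2,
        dimnames = list(c("x1", "x2"), c("n1", "n2")))
    expect_error(projectSamples(tt$model, alien), "no overlap")
    dropMost <- selectedGenes(tt$model)[
        -seq_len(round(0.2 * length(selectedGenes(tt$model))))]
    maskedMost <- expr[setdiff(rownames(expr), dropMost), , drop = FALSE]
    expect_warning(projectSamples(tt$model, maskedMost), "missing")
})

test_that("projection is per-sample linear: concatenation commutes", {
    tt <- trainTestAtlas()
    expr <- as.matrix(exprValues(tt$sim$expression))
    a <- expr[, 1:3]; b <- expr[, 4:6]
    pa <- projectSamples(tt$model, a)
    pb <- projectSamples(tt$model, b)
    pab <- projectSamples(tt$model, cbind(a, b))
    expect_equal(pab[, paste0("PC", 1:5)],
        rbind(pa, pb)[, paste0("PC", 1:5)])
})

test_that("held-out-platform samples project next to their own cell type", {
    sim <- simulateExpression(simConfig(nCelltypes = 5,
        fracMarkerPerCelltype = 0.04, effectSizeLog2 = 4, seed = 41))
    split <- heldoutSplit(sim$expression, "platform", "rnaseq_B")
    model <- fitAtlas(rankPercentile(split$train),
        buildConfig(0.2, 10))
    proj <- projectSamples(model, split$test)
    tc <- trainingCoords(model)[, 1:3]
    ct <- sim$truth$celltype[rownames(tc)]
    centroids <- rowsum(tc, ct) / as.vector(table(ct))
    d <- as.matrix(dist(rbind(centroids,
        as.matrix(proj[, c("PC1", "PC2", "PC3")]))))
    d <- d[-seq_len(nrow(centroids)), seq_len(nrow(centroids))]
    nearest <- rownames(centroids)[apply(d, 1, which.min)]
    truth <- unname(sim$truth$celltype[proj$sample_id])
    expect_gte(mean(nearest == truth), 0.9)
})

test_that("off-atlas scores are zero for training data and large off the cloud", {
    tt <- trainTestAtlas()
    res <- offAtlasScore(tt$model, trainingCoords(tt$model))
    expect_lt(max(res$score), 1e-6)
    expect_false(any(res$flag))
    # a point beyond the training range by 10x the diameter is flagged
    tc <- trainingCoords(tt$model)[, 1:3]
    diam <- max(dist(tc))
    far <- matrix(apply(tc, 2, max) + 10 * diam, 1)
    res2 <- offAtlasScore(tt$model, far)
    expect_true(res2$flag)
    expect_gt(res2$score, res2$cutoff)
})

test_that("profiles of unseen cell types are flagged more than held-out blood-like ones", {
    ratios <- vapply(1:3, function(seed) {
        sim <- simulateExpression(simConfig(nCelltypes = 8,
            fracMarkerPerCelltype = 0.05, effectSizeLog2 = 5,
            noiseSd = 0.8, seed = seed))
        split <- heldoutSplit(sim$expression, "dataset", "rnaseq_A_ds2")
        keep <- sprintf("celltype%02d", 1:5)
        inAtlas <- sampleAnnotation(split$train)$cell_type %in% keep
        model <- fitAtlas(rankPercentile(split$train[, inAtlas]),
            buildConfig(0.2, 10))
        testCt <- sampleAnnotation(split$test)$cell_type
        pin <- projectSamples(model, split$test[, testCt %in% keep])
        pout <- projectSamples(model, split$test[, !testCt %in% keep])
        mean(pout$off_atlas_flag) /
            max(mean(pin$off_atlas_flag), 1 / nrow(pin))
    }, numeric(1))
    expect_gte(median(ratios), 2)
})

test_that("pseudo-bulk pooling partitions clusters and conserves counts", {
    set.seed(9)
    counts <- matrix(rpois(20 * 60, 5), 20, 60,
        dimnames = list(paste0("g", 1:20), paste0("cell", 1:60)))
    labels <- rep(c("clusterA", "clusterB"), c(25, 35))
    pb <- suppressWarnings(
        pseudobulk(counts, labels, poolSize = 9, seed = 4))
    ann <- pb$annotation
    # floor(25/9) = 2 pools from A, floor(35/9) = 3 from B
    expect_identical(sum(ann$cluster == "clusterA"), 2L)
    expect_identical(sum(ann$cluster == "clusterB"), 3L)
    expect_true(all(ann$n_cells == 9))
    # counts conserved: every pool below the cluster total, sums match
    pm <- as.matrix(exprValues(pb$pools))
    expect_equal(sum(pm), sum(pm[, ann$sample_id]))
    expect_identical(valueKind(pb$pools), "raw")

    # one exact pool: sums equal the column sums of its cells
    one <- pseudobulk(counts[, 1:9], rep("c1", 9), poolSize = 9, seed = 1)
    expect_equal(unname(as.matrix(exprValues(one$pools))[, 1]),
        unname(rowSums(counts[, 1:9])))
    # poolSize 1: pools are the cells themselves (up to order)
    singles <- pseudobulk(counts[, 1:5], rep("c1", 5), poolSize = 1,
        seed = 1)
    expect_equal(unname(sort(colSums(as.matrix(exprValues(singles$pools))))),
        unname(sort(colSums(counts[, 1:5]))))
    # undersized cluster yields no pools, with a warning
    expect_warning(
        both <- pseudobulk(counts[, 1:12],
            rep(c("big", "tiny"), c(9, 3)), poolSize = 9, seed = 2),
        "tiny")
    expect_identical(nrow(both$annotation), 1L)
    expect_error(
        suppressWarnings(pseudobulk(counts[, 1:3], rep("t", 3),
            poolSize = 9)),
        "no pools")

    # keeping the remainder conserves all counts
    keep <- pseudobulk(counts[, 1:25], rep("cA", 25), poolSize = 9,
        dropRemainder = FALSE, seed = 4)
    expect_equal(sum(as.matrix(exprValues(keep$pools))),
        sum(counts[, 1:25]))
    expect_identical(keep$annotation$n_cells, c(9L, 9L, 7L))
})

test_that("pseudo-bulk pools of labelled 10x counts project like bulk", {
    sim <- simulateExpression(simConfig(nGenes = 400, nCelltypes = 3,
        samplesPerDatasetPerCelltype = 2, effectSizeLog2 = 5,
        fracMarkerPerCelltype = 0.06, seed = 14))
    pr <- rankPercentile(sim$expression)
    model <- fitAtlas(pr, buildConfig(0.2, 5))
    # synthesise cells: noisy integer thinnings of one RNA-seq sample per type
    set.seed(15)
    ann <- sampleAnnotation(sim$expression)
    cells <- list(); lab <- character()
    for (ct in unique(ann$cell_type)) {
        src <- as.matrix(exprValues(sim$expression))[,
            rownames(ann)[ann$cell_type == ct & ann$platform == "rnaseq_A"][1]]
        for (i in 1:18) {
            nm <- paste0(ct, "_cell", i)
            cells[[nm]] <- rbinom(length(src), round(src), 0.1)
            lab[nm] <- ct
        }
    }
    cm <- do.call(cbind, cells)
    rownames(cm) <- rownames(sim$expression)
    pb <- pseudobulk(cm, lab, poolSize = 9, seed = 16)
    proj <- projectSamples(model, pb$pools)
    tc <- trainingCoords(model)[, 1:3]
    centroids <- rowsum(tc, sim$truth$celltype[rownames(tc)]) /
        as.vector(table(sim$truth$celltype[rownames(tc)]))
    d <- as.matrix(dist(rbind(centroids,
        as.matrix(proj[, c("PC1", "PC2", "PC3")]))))
    d <- d[-seq_len(3), seq_len(3)]
    nearest <- rownames(centroids)[apply(d, 1, which.min)]
    expect_identical(unname(nearest), pb$annotation$cluster)
})
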