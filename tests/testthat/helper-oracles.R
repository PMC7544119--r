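suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

# brute-force average-rank percentile oracle: for each value, its 1-based
# average rank is (#{x < v} + 1 + #{x <= v}) / 2, enumerated directly
oracleRankPercentile <- function(x) {
    G <- length(x)
    r <- vapply(unname(x), function(v) (sum(x < v) + 1 + sum(x <= v)) / 2,
        numeric(1))
    unname((r - 1) / (G - 1))
}

# adjusted Rand index between two label vectors
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sc <- function(x) sum(choose(x, 2))
    exp <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
    (sc(tab) - exp) / (0.5 * (sc(rowSums(tab)) + sc(colSums(tab))) - exp)
}

# minimal annotation table for ad-hoc matrices
makeAnnotation <- function(sampleIds, platform,
                           dataset = paste0(platform, "_d1"), ...) {
    data.frame(sample_id = sampleIds, dataset_id = dataset,
        platform = platform, ..., stringsAsFactors = FALSE)
}

# gene-by-sample matrix of uniform noise with names
randomMatrix <- function(nGenes, nSamples, digits = NULL) {
    m <- matrix(stats::runif(nGenes * nSamples), nGenes, nSamples,
        dimnames = list(paste0("g", seq_len(nGenes)),
            paste0("s", seq_len(nSamples))))
    if (!is.null(digits)) m <- round(m, digits)
    m
}

# small percentile experiment with two platforms, for variance tests
twoPlatformExperiment <- function(values) {
    m <- matrix(values, nrow = 1,
        dimnames = list("g1", paste0("s", seq_along(values))))
    half <- length(values) / 2
    ann <- makeAnnotation(colnames(m),
        rep(c("A", "B"), each = half))
    AtlasExperiment(m, ann, valueKind = "raw")
}
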