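#' @describeIn rankPercentile transform every sample (column) of an
#'   [AtlasExperiment-class]; returns a percentile-kind experiment with the
#'   same annotation.
#'
#' Within each sample the gene with the highest expression maps to 1 and
#' the lowest to 0; values in between are uniformly spaced by rank,
#' percentile = (r - 1) / (G - 1) for 1-based average rank r over G genes.
#' Ties share the mean of their would-be ranks, so the exact zeros of
#' RNA-seq collapse to one shared low percentile with no special handling.
#' A fully tied (constant) sample maps to 0.5 everywhere. Each column is
#' transformed independently of all others, so adding new samples never
#' changes existing percentiles.
#' @export
setMethod("rankPercentile", "AtlasExperiment", function(x, ...) {
    if (identical(valueKind(x), "percentile"))
        stop("values are already rank percentiles")
    v <- rankPercentile(as.matrix(exprValues(x)))
    out <- AtlasExperiment(v, valueKind = "percentile")
    colData(out) <- colData(x)
    out
})

#' @describeIn rankPercentile transform the columns of a plain
#'   gene-by-sample numeric matrix.
#' @export
setMethod("rankPercentile", "matrix", function(x, ...) {
    G <- nrow(x)
    if (G < 2) stop("rank percentile transform needs at least 2 genes")
    if (!all(is.finite(x))) stop("non-finite expression values")
    apply(x, 2, function(col) (rank(col, ties.method = "average") - 1) /
        (G - 1))
})

#' Rank-percentile transform of a single expression vector
#'
#' Used by projection: a new sample is ranked over its own measured genes
#' (`universeSize` of them, at least the length of `values`) exactly as
#' [rankPercentile()] ranks training samples; atlas genes absent from the
#' new sample are later assigned percentile 0 (the lowest rank).
#'
#' @param values finite numeric vector (one sample's expression).
#' @param universeSize number of genes the ranks are scaled over; defaults
#'   to `length(values)`.
#' @return numeric vector of percentiles in \[0, 1\].
#' @examples
#' rankPercentileVector(c(5, 1, 3))  # 1.0 0.0 0.5
#' @export
rankPercentileVector <- function(values, universeSize = length(values)) {
    n <- length(values)
    if (n < 2) stop("need at least 2 values")
    if (universeSize < n)
        stop("universeSize (", universeSize, ") smaller than the number of ",
            "values (", n, ")")
    if (!all(is.finite(values))) stop("non-finite expression values")
    (rank(values, ties.method = "average") - 1) / (universeSize - 1)
}
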