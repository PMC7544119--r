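#' Read a gene-by-sample expression matrix
#'
#' Reads delimited text matrices (genes in rows, samples in columns, first
#' column holding the gene id — the common GEO series-matrix layout) or a
#' 10x-style MatrixMarket directory (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`; genes in rows). Zeros in sparse input are kept as exact
#' zeros. Gene and sample order follow the file.
#'
#' @param path file path (tsv/csv) or directory path (mtx_dir).
#' @param format one of `"tsv"`, `"csv"`, `"mtx_dir"`. Defaults from the
#'   file extension (directory implies `"mtx_dir"`).
#' @param samplesInRows set `TRUE` if the delimited file is transposed
#'   (samples in rows); the result is always genes x samples.
#'
#' @return An [AtlasExperiment-class] with `valueKind = "raw"`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(
#'     data.frame(gene_id = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4)),
#'     tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' dim(readExpression(tf))
#' @export
readExpression <- function(path, format = c("auto", "tsv", "csv", "mtx_dir"),
                           samplesInRows = FALSE) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (dir.exists(path)) "mtx_dir"
            else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
            else "tsv"
    }
    if (format == "mtx_dir") return(.readMtxDir(path))
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
            check.names = FALSE, comment.char = "#",
            stringsAsFactors = FALSE),
        error = function(e) stop("malformed ", format, " file '", path,
            "': ", conditionMessage(e), call. = FALSE))
    if (ncol(df) < 2) stop("expression file needs an id column plus at ",
        "least one value column: ", path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
        stop("non-numeric values in column '", colnames(df)[-1][bad],
            "' of ", path)
    }
    rownames(m) <- ids
    if (samplesInRows) m <- t(m)
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene ids in ", path, ": ",
            paste(utils::head(unique(rownames(m)[duplicated(rownames(m))]), 5),
                collapse = ", "))
    AtlasExperiment(m, valueKind = "raw")
}

.readMtxDir <- function(path) {
    if (!dir.exists(path)) stop("directory not found: ", path)
    pick <- function(names) {
        for (n in names) {
            f <- file.path(path, n)
            if (file.exists(f)) return(f)
        }
        stop("missing ", names[1], " in ", path)
    }
    mtx <- pick(c("matrix.mtx", "matrix.mtx.gz"))
    feat <- pick(c("features.tsv", "features.tsv.gz", "genes.tsv",
        "genes.tsv.gz"))
    bc <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    features <- utils::read.table(feat, sep = "\t", header = FALSE,
        stringsAsFactors = FALSE)
    barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
        stringsAsFactors = FALSE)[[1]]
    if (nrow(features) != nrow(m))
        stop("features.tsv has ", nrow(features), " rows but matrix has ",
            nrow(m))
    if (length(barcodes) != ncol(m))
        stop("barcodes.tsv has ", length(barcodes), " rows but matrix has ",
            ncol(m), " columns")
    rownames(m) <- features[[1]]
    colnames(m) <- barcodes
    if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", feat)
    AtlasExperiment(m, valueKind = "raw")
}

#' Read a sample annotation table
#'
#' Expects a delimited table with at least `sample_id`, `dataset_id` and
#' `platform` columns; `cell_type`, `progenitor_type` and `sample_source`
#' are recognised optional columns (any further columns are carried along).
#' Empty strings and `"NA"` in optional columns become `NA`.
#'
#' @param path CSV or TSV file (separator sniffed from the header line).
#' @return A [S4Vectors::DataFrame] keyed by `sample_id` row names.
#' @export
readAnnotation <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
        stringsAsFactors = FALSE, quote = "\"", comment.char = "#")
    mandatory <- c("sample_id", "dataset_id", "platform")
    miss <- setdiff(mandatory, colnames(df))
    if (length(miss))
        stop("annotation is missing mandatory column(s): ",
            paste(miss, collapse = ", "))
    for (col in mandatory) {
        v <- as.character(df[[col]])
        if (any(is.na(v) | v == ""))
            stop("annotation column '", col, "' has empty entries")
        df[[col]] <- v
    }
    for (col in setdiff(colnames(df), mandatory)) {
        if (is.character(df[[col]]))
            df[[col]][df[[col]] %in% c("", "NA")] <- NA
    }
    if ("sample_source" %in% colnames(df)) {
        ok <- is.na(df$sample_source) |
            df$sample_source %in% c("in_vivo", "ex_vivo", "in_vitro")
        if (!all(ok))
            stop("sample_source must be one of in_vivo, ex_vivo, in_vitro")
    }
    .asAnnotation(df)
}

#' Save / load a fitted atlas
#'
#' An atlas is stored as a directory of human-inspectable plain-text tables
#' plus a JSON config: `config.json` (threshold, components, explained
#' variances, provenance), `genes.tsv`, `gene_means.tsv`, `loadings.tsv`
#' (genes x components) and `coords.tsv` (training samples x components).
#' The round trip is lossless to better than 1e-12 on reals.
#'
#' @param model an [AtlasModel-class].
#' @param dir directory to create/read.
#' @return `saveAtlas` invisibly returns `dir`; `loadAtlas` returns the
#'   reconstructed [AtlasModel-class].
#' @export
saveAtlas <- function(model, dir) {
    stopifnot(is(model, "AtlasModel"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    k <- model@nComponents
    pcs <- paste0("PC", seq_len(k))
    cfg <- list(
        threshold = model@threshold,
        n_components = k,
        explained_variance = model@explainedVariance,
        provenance = model@provenance
    )
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(model@selectedGenes, file.path(dir, "genes.tsv"))
    .writeTsv(data.frame(gene_id = model@selectedGenes,
        mean_percentile = unname(model@geneMeans)),
        file.path(dir, "gene_means.tsv"))
    ld <- as.data.frame(t(model@loadings))
    colnames(ld) <- pcs
    .writeTsv(cbind(data.frame(gene_id = model@selectedGenes), ld),
        file.path(dir, "loadings.tsv"))
    co <- as.data.frame(model@trainingCoords)
    colnames(co) <- pcs
    .writeTsv(cbind(data.frame(sample_id = rownames(model@trainingCoords)),
        co), file.path(dir, "coords.tsv"))
    invisible(dir)
}

#' @rdname saveAtlas
#' @export
loadAtlas <- function(dir) {
    need <- c("config.json", "genes.tsv", "gene_means.tsv", "loadings.tsv",
        "coords.tsv")
    for (f in need)
        if (!file.exists(file.path(dir, f)))
            stop("atlas directory ", dir, " is missing ", f)
    cfg <- jsonlite::read_json(file.path(dir, "config.json"),
        simplifyVector = TRUE)
    genes <- readLines(file.path(dir, "genes.tsv"))
    means <- utils::read.table(file.path(dir, "gene_means.tsv"),
        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    ld <- utils::read.table(file.path(dir, "loadings.tsv"), header = TRUE,
        sep = "\t", stringsAsFactors = FALSE)
    co <- utils::read.table(file.path(dir, "coords.tsv"), header = TRUE,
        sep = "\t", stringsAsFactors = FALSE)
    gm <- stats::setNames(means$mean_percentile, means$gene_id)[genes]
    loadings <- t(as.matrix(ld[, -1, drop = FALSE]))
    colnames(loadings) <- ld$gene_id
    rownames(loadings) <- NULL
    coords <- as.matrix(co[, -1, drop = FALSE])
    rownames(coords) <- co$sample_id
    colnames(coords) <- colnames(ld)[-1]
    prov <- cfg$provenance
    if (is.null(prov)) prov <- list()
    new("AtlasModel",
        selectedGenes = genes,
        geneMeans = gm,
        loadings = loadings,
        explainedVariance = as.numeric(cfg$explained_variance),
        trainingCoords = coords,
        threshold = as.numeric(cfg$threshold),
        nComponents = as.integer(cfg$n_components),
        provenance = as.list(prov))
}

# full-precision TSV writer shared by atlas serialization and the CLI
.writeTsv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
}
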