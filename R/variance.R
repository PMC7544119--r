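#' Per-gene fraction of variance attributable to platform
#'
#' Fits, for every gene, the one-way fixed-effect model
#' `y = X_p beta_p + e` where `X_p` encodes platform membership of each
#' sample, and reports `sigma2_platform = var(X_p beta_p)` (variance of the
#' fitted platform means), `sigma2_resid = var(e)` and their ratio
#' `fraction_platform = sigma2_platform / (sigma2_platform + sigma2_resid)`.
#' Population (divide-by-n) variances are used throughout, which makes the
#' fraction exactly the R-squared of the platform regression and so
#' independent of the variance convention. A constant gene (0/0) gets
#' fraction 0.
#'
#' The computation is the closed-form group-means ANOVA, vectorised over
#' genes; no per-gene model object is built.
#'
#' @param x an [AtlasExperiment-class] with percentile values (any numeric
#'   values are accepted; percentiles are what the atlas pipeline passes).
#' @param annotation per-sample annotation with a `platform` column;
#'   defaults to `colData(x)`. Must cover every sample of `x`.
#' @return data.frame with columns `gene_id`, `sigma2_platform`,
#'   `sigma2_resid`, `fraction_platform`, in the gene order of `x`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 3, 4, 5))
#' m <- rbind(m, g2 = c(1, 2, 3, 1, 2, 3))
#' colnames(m) <- paste0("s", 1:6)
#' ann <- data.frame(sample_id = colnames(m),
#'     dataset_id = "d1", platform = rep(c("A", "B"), each = 3))
#' ae <- AtlasExperiment(m, ann)
#' platformVarianceFraction(ae)$fraction_platform  # 0.6, 0
#' @export
platformVarianceFraction <- function(x, annotation = NULL) {
    v <- .alignedValues(x, annotation)
    platform <- v$platform
    m <- v$values
    if (length(unique(platform)) < 2)
        stop("platform effect unidentifiable: need at least 2 platforms")
    singletons <- names(which(table(platform) == 1))
    if (length(singletons))
        warning("platform(s) with a single sample (fitted mean absorbs ",
            "the sample, inflating the platform fraction): ",
            paste(singletons, collapse = ", "))
    n <- ncol(m)
    overall <- rowMeans(m)
    ssTotal <- rowSums((m - overall)^2)
    fitted <- matrix(0, nrow(m), n)
    for (p in unique(platform)) {
        idx <- which(platform == p)
        fitted[, idx] <- rowMeans(m[, idx, drop = FALSE])
    }
    ssBetween <- rowSums((fitted - overall)^2)
    ssResid <- ssTotal - ssBetween
    frac <- ifelse(ssTotal > 0, ssBetween / ssTotal, 0)
    data.frame(
        gene_id = rownames(m),
        sigma2_platform = ssBetween / n,
        sigma2_resid = pmax(ssResid, 0) / n,
        fraction_platform = pmin(pmax(frac, 0), 1),
        row.names = NULL, stringsAsFactors = FALSE)
}

# align an experiment's columns with an annotation table and pull the
# factors the variance models need
.alignedValues <- function(x, annotation, fields = "platform") {
    if (is(x, "AtlasExperiment")) {
        if (is.null(annotation)) annotation <- colData(x)
        m <- as.matrix(exprValues(x))
    } else {
        m <- as.matrix(x)
        if (is.null(annotation)) stop("annotation required for plain matrices")
    }
    ann <- .asAnnotation(annotation)
    miss <- setdiff(colnames(m), rownames(ann))
    if (length(miss))
        stop("samples without annotation: ",
            paste(utils::head(miss, 5), collapse = ", "))
    ann <- ann[colnames(m), , drop = FALSE]
    out <- list(values = m)
    for (f in fields) {
        if (!f %in% colnames(ann))
            stop("annotation lacks required column '", f, "'")
        val <- as.character(ann[[f]])
        if (any(is.na(val)))
            stop("annotation column '", f, "' has missing values")
        out[[f]] <- val
    }
    out
}

#' Class versus platform variance components per gene
#'
#' Diagnostic contrasting biological signal with platform signal: for each
#' gene the percentile values are mapped into the open unit interval with
#' the continuity correction p' = (p (G - 1) + 0.5) / G (G = number of
#' genes), probit-transformed with `qnorm`, and a two-random-intercept
#' linear mixed model `y ~ 1 + (1 | class) + (1 | platform)` is fitted by
#' REML with [lme4::lmer]. The class factor is one of `cell_type`,
#' `progenitor_type` or `sample_source`. Genes are orderable by the
#' class/platform variance ratio; a zero platform component with a positive
#' class component yields `Inf`.
#'
#' Genes for which the fit fails (e.g. constant expression) are returned
#' with `converged = FALSE` and `NA` components rather than dropped.
#'
#' @param x an [AtlasExperiment-class] with percentile values.
#' @param classField which annotation column plays the class role.
#' @param annotation optional annotation override (defaults to
#'   `colData(x)`); needs `platform` and the class column, non-missing.
#' @return data.frame with columns `gene_id`, `sigma2_class`,
#'   `sigma2_platform`, `sigma2_resid`, `prop_class`, `prop_platform`,
#'   `prop_resid`, `class_platform_ratio`, `converged`.
#' @export
lmmClassPlatform <- function(x,
        classField = c("cell_type", "progenitor_type", "sample_source"),
        annotation = NULL) {
    classField <- match.arg(classField)
    v <- .alignedValues(x, annotation, fields = c("platform", classField))
    m <- v$values
    G <- nrow(m)
    platform <- factor(v$platform)
    cls <- factor(v[[classField]])
    if (nlevels(platform) < 2 || nlevels(cls) < 2)
        stop("need at least 2 levels in both class and platform")
    probit <- stats::qnorm((m * (G - 1) + 0.5) / G)
    df <- data.frame(class = cls, platform = platform)
    fits <- lapply(seq_len(G), function(i) {
        df$y <- probit[i, ]
        if (stats::var(df$y) == 0)   # constant gene: components undefined
            return(c(NA_real_, NA_real_, NA_real_))
        fit <- tryCatch(
            suppressMessages(suppressWarnings(
                lme4::lmer(y ~ 1 + (1 | class) + (1 | platform), data = df,
                    REML = TRUE))),
            error = function(e) NULL)
        if (is.null(fit))
            return(c(NA_real_, NA_real_, NA_real_))
        vc <- as.data.frame(lme4::VarCorr(fit))
        get <- function(g) vc$vcov[match(g, vc$grp)]
        c(get("class"), get("platform"), get("Residual"))
    })
    comp <- do.call(rbind, fits)
    tot <- rowSums(comp)
    ratio <- ifelse(comp[, 2] > 0, comp[, 1] / comp[, 2],
        ifelse(comp[, 1] > 0, Inf, 0))
    data.frame(
        gene_id = rownames(m),
        sigma2_class = comp[, 1],
        sigma2_platform = comp[, 2],
        sigma2_resid = comp[, 3],
        prop_class = comp[, 1] / tot,
        prop_platform = comp[, 2] / tot,
        prop_resid = comp[, 3] / tot,
        class_platform_ratio = ratio,
        converged = !is.na(comp[, 1]),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Histogram of platform-variance fractions
#'
#' @param genevar data.frame from [platformVarianceFraction()].
#' @param bins number of equal-width bins over \[0, 1\].
#' @return data.frame with `bin_low`, `bin_high`, `count`; counts sum to
#'   the number of genes.
#' @export
varianceFractionHistogram <- function(genevar, bins = 20) {
    if (!nrow(genevar)) stop("empty variance table")
    if (bins < 1) stop("bins must be >= 1")
    breaks <- seq(0, 1, length.out = bins + 1)
    idx <- findInterval(genevar$fraction_platform, breaks,
        rightmost.closed = TRUE, all.inside = TRUE)
    data.frame(
        bin_low = breaks[-(bins + 1)],
        bin_high = breaks[-1],
        count = tabulate(idx, nbins = bins))
}
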