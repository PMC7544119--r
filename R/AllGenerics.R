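#' @rdname AtlasExperiment-class
#' @param x an object.
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname AtlasExperiment-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname AtlasExperiment-class
#' @export
setGeneric("sampleAnnotation",
    function(x) standardGeneric("sampleAnnotation"))

#' Transform expression values to per-sample rank percentiles
#'
#' @param x an [AtlasExperiment-class] with raw values, or a numeric
#'   gene-by-sample matrix.
#' @param ... unused.
#' @export
setGeneric("rankPercentile", function(x, ...) standardGeneric("rankPercentile"))

#' @rdname AtlasModel-class
#' @param x an object.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname AtlasModel-class
#' @export
setGeneric("geneMeans", function(x) standardGeneric("geneMeans"))

#' @rdname AtlasModel-class
#' @export
setGeneric("atlasLoadings", function(x) standardGeneric("atlasLoadings"))

#' @rdname AtlasModel-class
#' @export
setGeneric("explainedVariance",
    function(x) standardGeneric("explainedVariance"))

#' @rdname AtlasModel-class
#' @export
setGeneric("trainingCoords", function(x) standardGeneric("trainingCoords"))

#' @rdname StabilityReport-class
#' @param x an object.
#' @export
setGeneric("medianH", function(x) standardGeneric("medianH"))
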