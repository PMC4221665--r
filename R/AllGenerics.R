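#' @rdname ParameterCatalog-class
#' @param object,x a \code{ParameterCatalog}, \code{ZScoreMatrix} or
#'   \code{PCModel} as appropriate.
#' @export
setGeneric("paramIds", function(x) standardGeneric("paramIds"))

#' @rdname ParameterCatalog-class
#' @export
setGeneric("paramInfo", function(x) standardGeneric("paramInfo"))

#' @rdname ParameterCatalog-class
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("referenceStrain", function(x) standardGeneric("referenceStrain"))

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("droppedParams", function(x) standardGeneric("droppedParams"))

#' @rdname PCModel-class
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname PCModel-class
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname PCModel-class
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))

#' @rdname PCModel-class
#' @export
setGeneric("propVarExplained", function(x) standardGeneric("propVarExplained"))

## ---- methods -------------------------------------------------------------

#' @rdname ParameterCatalog-class
#' @export
setMethod("paramIds", "ParameterCatalog", function(x) x@params$param_id)

#' @rdname ParameterCatalog-class
#' @export
setMethod("paramInfo", "ParameterCatalog", function(x) x@params)

#' @rdname ParameterCatalog-class
#' @export
setMethod("nParams", "ParameterCatalog", function(x) nrow(x@params))

#' @export
#' @rdname ParameterCatalog-class
setMethod("show", "ParameterCatalog", function(object) {
    tab <- table(factor(object@params$family, levels = TRAIT_FAMILIES))
    cat("ParameterCatalog with", nrow(object@params), "parameters\n")
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname ZScoreMatrix-class
#' @export
setMethod("zMatrix", "ZScoreMatrix", function(x) x@z)

#' @rdname ZScoreMatrix-class
#' @export
setMethod("referenceStrain", "ZScoreMatrix", function(x) x@reference)

#' @rdname ZScoreMatrix-class
#' @export
setMethod("droppedParams", "ZScoreMatrix", function(x) x@dropped)

#' @rdname ZScoreMatrix-class
#' @export
setMethod("dim", "ZScoreMatrix", function(x) dim(x@z))

#' @rdname ZScoreMatrix-class
#' @export
setMethod("show", "ZScoreMatrix", function(object) {
    cat("ZScoreMatrix:", nrow(object@z), "strains x", ncol(object@z),
        "parameters (reference:", object@reference, ")\n")
    if (length(object@dropped))
        cat("  dropped parameters:", length(object@dropped), "\n")
})

#' @rdname PCModel-class
#' @export
setMethod("pcScores", "PCModel", function(x) x@scores)

#' @rdname PCModel-class
#' @export
setMethod("pcLoadings", "PCModel", function(x) x@loadings)

#' @rdname PCModel-class
#' @export
setMethod("varExplained", "PCModel", function(x) x@varExplained)

#' @rdname PCModel-class
#' @export
setMethod("propVarExplained", "PCModel",
    function(x) x@varExplained / sum(x@varExplained))

#' @rdname PCModel-class
#' @export
setMethod("show", "PCModel", function(object) {
    p <- cumsum(propVarExplained(object))
    cat("PCModel:", nrow(object@scores), "strains,", ncol(object@scores),
        "components\n")
    k <- min(4L, length(p))
    cat("  cumulative variance (PC1..PC", k, "): ",
        paste(sprintf("%.3f", p[seq_len(k)]), collapse = " "), "\n", sep = "")
})
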