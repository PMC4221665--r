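#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

TRAIT_FAMILIES <- c("gaussian_cv", "gamma", "beta", "binomial_od")
TRAIT_LINKS <- c("identity", "log", "logit")

#' Catalog of CalMorph-style morphological parameters
#'
#' A \code{ParameterCatalog} stores one descriptor per morphological trait:
#' its identifier, probability family, link function, and -- for
#' coefficient-of-variation (CV) traits -- the identifier of the paired mean
#' trait whose value the CV depends on.
#'
#' @slot params \code{data.frame} with columns \code{param_id},
#'   \code{family} (one of \code{gaussian_cv}, \code{gamma}, \code{beta},
#'   \code{binomial_od}), \code{link} (one of \code{identity}, \code{log},
#'   \code{logit}), \code{mean_partner_id} (non-empty iff family is
#'   \code{gaussian_cv}) and \code{description}.
#'
#' @seealso [buildDefaultCatalog()], [readParameterCatalog()]
#' @export
setClass("ParameterCatalog", slots = c(params = "data.frame"))

setValidity("ParameterCatalog", function(object) {
    p <- object@params
    need <- c("param_id", "family", "link", "mean_partner_id", "description")
    if (!all(need %in% colnames(p)))
        return(paste("missing columns:", paste(setdiff(need, colnames(p)), collapse = ", ")))
    if (anyDuplicated(p$param_id))
        return("duplicated param_id")
    if (!all(p$family %in% TRAIT_FAMILIES))
        return("unknown family")
    if (!all(p$link %in% TRAIT_LINKS))
        return("unknown link")
    cv <- p$family == "gaussian_cv"
    if (any(cv & (is.na(p$mean_partner_id) | p$mean_partner_id == "")))
        return("gaussian_cv parameters must declare a mean_partner_id")
    if (!all(p$mean_partner_id[cv] %in% p$param_id))
        return("mean_partner_id not present in catalog")
    TRUE
})

#' Replicate-level morphological trait table
#'
#' A \code{MorphoSet} extends \linkS4class{SummarizedExperiment}: rows are
#' morphological parameters (with the catalog descriptor in \code{rowData}),
#' columns are cultures. The \code{"value"} assay holds the trait values
#' (success counts for overdispersed-binomial traits); the \code{"trials"}
#' assay holds the number of cells scored per culture for binomial traits
#' (\code{NA} elsewhere). \code{colData} carries \code{strain_id},
#' \code{group} (\code{wildtype}, \code{natural} or \code{deletion}) and
#' \code{replicate_index}.
#'
#' @seealso [simulateMorphology()], [readTraitTable()], [validateTraitTable()]
#' @export
setClass("MorphoSet", contains = "SummarizedExperiment")

setValidity("MorphoSet", function(object) {
    if (!"value" %in% SummarizedExperiment::assayNames(object))
        return("assay 'value' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("strain_id", "group", "replicate_index")
    if (!all(need %in% colnames(cd)))
        return(paste("colData must contain", paste(need, collapse = ", ")))
    if (!all(cd$group %in% c("wildtype", "natural", "deletion")))
        return("group must be wildtype, natural or deletion")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("param_id", "family") %in% colnames(rd)))
        return("rowData must contain param_id and family")
    TRUE
})

#' Strain-by-parameter matrix of GLM Wald Z-scores
#'
#' Each entry is the Wald statistic of the strain-effect coefficient in a
#' two-group GLM of one trait against the wild-type reference cultures.
#'
#' @slot z numeric matrix, strains in rows, parameters in columns.
#' @slot reference identifier of the reference (wild-type) strain group.
#' @slot dropped parameters discarded because at least one fit failed or a
#'   value was missing.
#' @slot provenance character, hash of the catalog the scores were fit
#'   against.
#'
#' @seealso [zscoreMatrix()]
#' @export
setClass("ZScoreMatrix",
    slots = c(z = "matrix", reference = "character",
              dropped = "character", provenance = "character"))

setValidity("ZScoreMatrix", function(object) {
    z <- object@z
    if (is.null(rownames(z)) || is.null(colnames(z)))
        return("z must have strain rownames and parameter colnames")
    if (anyDuplicated(rownames(z)) || anyDuplicated(colnames(z)))
        return("duplicated strain or parameter labels")
    if (ncol(z) > 0 && any(apply(z, 2, function(x) all(is.na(x)))))
        return("column of all-missing values")
    TRUE
})

#' Principal-component model of a Z-score matrix
#'
#' Column-centered, unscaled PCA of the strain-by-parameter Z-score matrix
#' (i.e. an eigendecomposition of its variance-covariance matrix).
#'
#' @slot loadings parameter x component rotation matrix.
#' @slot scores strain x component score matrix.
#' @slot varExplained per-component variance of the scores.
#' @slot center column means removed before rotation.
#'
#' @seealso [pcaZ()]
#' @export
setClass("PCModel",
    slots = c(loadings = "matrix", scores = "matrix",
              varExplained = "numeric", center = "numeric"))

setValidity("PCModel", function(object) {
    if (ncol(object@loadings) != ncol(object@scores))
        return("loadings and scores disagree on component count")
    if (length(object@varExplained) != ncol(object@scores))
        return("varExplained length must equal component count")
    if (is.unsorted(rev(object@varExplained + 1e-12)))
        return("explained variance must be non-increasing")
    TRUE
})
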