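## Default trait catalog and trait-table validation.

DEFAULT_LINKS <- c(gaussian_cv = "identity", gamma = "log",
                   beta = "logit", binomial_od = "logit")

## Counts of the four probability families among the 501 CalMorph parameters.
FAMILY_COUNTS <- c(gaussian_cv = 220L, gamma = 183L, beta = 37L,
                   binomial_od = 61L)

#' Build the default 501-parameter catalog
#'
#' Constructs a deterministic catalog of 501 CalMorph-style morphological
#' parameters partitioned into the four probability families used by the
#' normalization GLM: 220 coefficient-of-variation (CV) traits treated as
#' Gaussian after Lowess uncoupling, 183 positive continuous traits treated
#' as gamma, 37 unit-interval traits treated as beta, and 61 cell-ratio
#' traits treated as binomial with overdispersion.
#'
#' Identifiers follow the CalMorph naming style (\code{C*} cell-shape,
#' \code{A*} actin, \code{D*} nuclear traits; \code{CCV*} for CV traits) but
#' are synthetic: the published identifier-to-family table is not shipped.
#' Each CV trait is paired one-to-one with a mean trait (the 183 gamma plus
#' 37 beta traits, 220 in total), reproducing CalMorph's mean/CV pairing.
#' Real CalMorph exports can be analyzed by supplying a user catalog via
#' [readParameterCatalog()].
#'
#' @return A \linkS4class{ParameterCatalog} with exactly 501 descriptors.
#' @examples
#' cat501 <- buildDefaultCatalog()
#' table(paramInfo(cat501)$family)
#' @export
buildDefaultCatalog <- function() {
    gammaIds <- sprintf("C%d_A", 100 + seq_len(FAMILY_COUNTS["gamma"]))
    betaIds  <- sprintf("A%d_B", 100 + seq_len(FAMILY_COUNTS["beta"]))
    binomIds <- sprintf("D%d_C", 100 + seq_len(FAMILY_COUNTS["binomial_od"]))
    meanIds <- c(gammaIds, betaIds)
    cvIds <- paste0("CCV", substring(meanIds, 2))

    params <- rbind(
        data.frame(param_id = gammaIds, family = "gamma",
                   mean_partner_id = "",
                   description = "mean cell-shape trait (positive continuous)"),
        data.frame(param_id = betaIds, family = "beta",
                   mean_partner_id = "",
                   description = "mean actin trait (unit interval)"),
        data.frame(param_id = binomIds, family = "binomial_od",
                   mean_partner_id = "",
                   description = "ratio of cells in specimen (count / trials)"),
        data.frame(param_id = cvIds, family = "gaussian_cv",
                   mean_partner_id = meanIds,
                   description = "cell-to-cell noise (CV of paired mean trait)")
    )
    params$link <- unname(DEFAULT_LINKS[params$family])
    params <- params[, c("param_id", "family", "link", "mean_partner_id",
                         "description")]
    rownames(params) <- NULL
    methods::new("ParameterCatalog", params = params)
}

#' Construct a catalog from a descriptor data.frame
#'
#' @param params data.frame with columns \code{param_id}, \code{family} and
#'   optionally \code{link}, \code{mean_partner_id}, \code{description};
#'   missing links default to the canonical link of each family.
#' @return A \linkS4class{ParameterCatalog}.
#' @export
ParameterCatalog <- function(params) {
    params <- as.data.frame(params)
    if (is.null(params$link) || all(is.na(params$link)))
        params$link <- unname(DEFAULT_LINKS[params$family])
    if (is.null(params$mean_partner_id)) params$mean_partner_id <- ""
    params$mean_partner_id[is.na(params$mean_partner_id)] <- ""
    if (is.null(params$description)) params$description <- ""
    methods::new("ParameterCatalog",
                 params = params[, c("param_id", "family", "link",
                                     "mean_partner_id", "description")])
}

## support check for one family; returns character(0) or issue strings
.supportIssues <- function(values, family, trials = NULL) {
    v <- values[!is.na(values)]
    issues <- character(0)
    if (family == "gamma" && any(v <= 0))
        issues <- c(issues, "non-positive value for gamma trait")
    if (family == "beta") {
        if (any(v == 0 | v == 1))
            issues <- c(issues, "boundary value (exactly 0 or 1) for beta trait")
        if (any(v < 0 | v > 1))
            issues <- c(issues, "value outside (0,1) for beta trait")
    }
    if (family == "binomial_od") {
        if (any(v < 0) || any(v != round(v)))
            issues <- c(issues, "binomial trait values must be nonnegative counts")
        if (!is.null(trials)) {
            t <- trials[!is.na(values)]
            if (any(is.na(t)))
                issues <- c(issues, "missing trial counts for binomial trait")
            else if (any(v > t))
                issues <- c(issues, "count exceeds trials for binomial trait")
        } else {
            issues <- c(issues, "no trials recorded for binomial trait")
        }
    }
    issues
}

#' Validate a trait table against a catalog
#'
#' Checks every parameter of a \linkS4class{MorphoSet} against the family
#' support declared in the catalog (gamma traits strictly positive, beta
#' traits in the open unit interval, binomial traits as counts bounded by
#' their trial numbers) and lists parameters that would be dropped because a
#' value is missing for some culture.
#'
#' @param table a \linkS4class{MorphoSet}.
#' @param catalog a \linkS4class{ParameterCatalog}; every parameter of
#'   \code{table} must be present in it (unknown identifiers are an error).
#' @return A list with elements \code{violations} (data.frame of
#'   \code{param_id}, \code{issue}), \code{dropped} (parameter ids with
#'   missing values), \code{n_dropped} and \code{ok}.
#' @export
validateTraitTable <- function(table, catalog) {
    stopifnot(methods::is(table, "MorphoSet"),
              methods::is(catalog, "ParameterCatalog"))
    rd <- SummarizedExperiment::rowData(table)
    unknown <- setdiff(rd$param_id, paramIds(catalog))
    if (length(unknown))
        stop("parameters absent from catalog: ",
             paste(unknown, collapse = ", "))
    fam <- paramInfo(catalog)$family[match(rd$param_id, paramIds(catalog))]
    vals <- SummarizedExperiment::assay(table, "value")
    trials <- if ("trials" %in% SummarizedExperiment::assayNames(table))
        SummarizedExperiment::assay(table, "trials") else NULL

    viols <- list()
    dropped <- character(0)
    for (i in seq_along(rd$param_id)) {
        pid <- rd$param_id[i]
        iss <- .supportIssues(vals[i, ], fam[i],
                              if (!is.null(trials)) trials[i, ] else NULL)
        if (length(iss))
            viols[[pid]] <- data.frame(param_id = pid, issue = iss)
        if (anyNA(vals[i, ])) dropped <- c(dropped, pid)
    }
    violations <- if (length(viols)) do.call(rbind, c(viols, make.row.names = FALSE))
        else data.frame(param_id = character(0), issue = character(0))
    if (length(dropped))
        message(length(dropped),
                " parameter(s) have missing values and would be dropped")
    list(violations = violations, dropped = dropped,
         n_dropped = length(dropped),
         ok = nrow(violations) == 0L && length(dropped) == 0L)
}
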