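## Trait normalization: Lowess uncoupling of CV traits, per-strain GLM fits,
## and the strain x parameter Wald Z-score matrix.

#' Remove the CV--mean dependence by Lowess regression
#'
#' Coefficient-of-variation traits depend strongly on their paired mean
#' trait. For each CV parameter this fits a locally weighted regression
#' (\code{stats::lowess}) of the CV values on the partner mean values across
#' cultures with smoother span \code{span}, and replaces the CV values by
#' the residuals, which are treated as Gaussian downstream.
#'
#' @param table a \linkS4class{MorphoSet}.
#' @param span Lowess smoother span (default 0.4).
#' @param scope fit the trend on all cultures (\code{"global"}, default) or
#'   on the reference group only (\code{"reference"}); residuals are always
#'   computed for all cultures.
#' @param reference group label used when \code{scope = "reference"}.
#' @return The \code{MorphoSet} with CV rows replaced by residuals.
#' @export
normalizeCV <- function(table, span = 0.4, scope = c("global", "reference"),
                        reference = "wildtype") {
    scope <- match.arg(scope)
    rd <- SummarizedExperiment::rowData(table)
    vals <- SummarizedExperiment::assay(table, "value")
    trials <- SummarizedExperiment::assay(table, "trials")
    fitCols <- if (scope == "reference")
        SummarizedExperiment::colData(table)$group == reference
    else rep(TRUE, ncol(vals))

    for (i in which(rd$family == "gaussian_cv")) {
        j <- match(rd$mean_partner_id[i], rd$param_id)
        if (is.na(j))
            stop("CV parameter ", rd$param_id[i], " needs partner column ",
                 rd$mean_partner_id[i])
        x <- vals[j, ]
        if (rd$family[j] == "binomial_od") x <- x / trials[j, ]
        y <- vals[i, ]
        use <- fitCols & !is.na(x) & !is.na(y)
        if (sum(use) < 2)
            stop("too few cultures to fit the CV trend for ", rd$param_id[i])
        ## delta = 0: evaluate the smoother at every culture rather than
        ## interpolating between anchor points
        lo <- stats::lowess(x[use], y[use], f = span, delta = 0)
        pred <- stats::approx(lo$x, lo$y, xout = x, rule = 2, ties = mean)$y
        vals[i, ] <- y - pred
    }
    SummarizedExperiment::assay(table, "value") <- vals
    table
}

#' Fit the two-group GLM for one strain and one trait
#'
#' Fits \eqn{\eta(E[y]) = \beta_0 + \beta_1 x} with \eqn{x} the 0/1
#' wild-type/mutant indicator, by the family-appropriate likelihood: a
#' Gaussian linear model for Lowess-normalized CV traits, a gamma GLM, a
#' mean-precision beta regression (common precision across groups), or a
#' quasi-binomial GLM whose standard errors carry the Pearson-based
#' dispersion estimate. The Wald statistic \eqn{\beta_1 / se(\beta_1)} is
#' the trait's Z-score.
#'
#' @param refValues reference (wild-type) culture values; at least 2.
#' @param strainValues mutant culture values; at least 1. With a single
#'   culture the dispersion is estimated from the pooled residuals, which
#'   are dominated by the reference.
#' @param family one of \code{gaussian_cv}, \code{gamma}, \code{beta},
#'   \code{binomial_od}.
#' @param link link function; defaults to the family's canonical choice
#'   (identity, log, logit, logit).
#' @param refTrials,strainTrials per-culture trial counts, required for
#'   \code{binomial_od}.
#' @return list with \code{beta0}, \code{beta1}, \code{se_beta1}, \code{z},
#'   \code{fitted_mean} (response scale), \code{fitted_link} (link scale)
#'   and \code{converged}.
#' @export
fitStrainEffect <- function(refValues, strainValues, family,
                            link = NULL,
                            refTrials = NULL, strainTrials = NULL) {
    stopifnot(family %in% TRAIT_FAMILIES)
    if (is.null(link)) link <- unname(DEFAULT_LINKS[family])
    refValues <- refValues[!is.na(refValues)]
    strainValues <- strainValues[!is.na(strainValues)]
    if (length(refValues) < 2 || length(strainValues) < 1)
        stop("need >= 2 reference and >= 1 strain culture")
    y <- c(refValues, strainValues)
    x <- c(rep(0, length(refValues)), rep(1, length(strainValues)))

    if (family == "gamma" && any(y <= 0))
        stop("gamma trait values must be strictly positive")
    if (family == "beta" && any(y <= 0 | y >= 1))
        stop("beta trait values must lie in the open interval (0, 1)")

    fail <- list(beta0 = NA_real_, beta1 = NA_real_, se_beta1 = NA_real_,
                 z = NA_real_, fitted_mean = NA_real_,
                 fitted_link = NA_real_, converged = FALSE)
    if (stats::var(y) == 0) return(fail)

    fit <- tryCatch(suppressWarnings(switch(family,
        gaussian_cv = stats::lm(y ~ x),
        gamma = stats::glm(y ~ x, family = stats::Gamma(link = link),
                           control = stats::glm.control(maxit = 100,
                                                        epsilon = 1e-8)),
        beta = mgcv::gam(y ~ x,
                         family = do.call(mgcv::betar, list(link = link))),
        binomial_od = {
            trials <- c(refTrials, strainTrials)
            if (is.null(trials) || length(trials) != length(y))
                stop("binomial_od requires trial counts for every culture")
            if (any(y < 0 | y > trials))
                stop("binomial counts must lie in [0, trials]")
            stats::glm(cbind(y, trials - y) ~ x,
                       family = stats::quasibinomial(link = link),
                       control = stats::glm.control(maxit = 100,
                                                    epsilon = 1e-8))
        })), error = function(e) NULL)
    if (is.null(fit)) return(fail)

    ct <- if (inherits(fit, "gam")) summary(fit)$p.table
          else stats::coef(summary(fit))
    if (!"x" %in% rownames(ct) || anyNA(ct["x", 1:2])) return(fail)
    beta0 <- ct[1, 1]; beta1 <- ct["x", 1]; se <- ct["x", 2]
    if (!is.finite(se) || se <= 0) return(fail)
    linkFun <- stats::make.link(link)
    list(beta0 = beta0, beta1 = beta1, se_beta1 = se, z = beta1 / se,
         fitted_mean = linkFun$linkinv(beta0 + beta1),
         fitted_link = beta0 + beta1,
         converged = if (!is.null(fit$converged)) isTRUE(fit$converged) else TRUE)
}

.fitRow <- function(vals, trials, cdStrain, refIdx, strain, family, link) {
    sIdx <- cdStrain == strain
    fitStrainEffect(vals[refIdx], vals[sIdx], family, link,
                    refTrials = if (family == "binomial_od") trials[refIdx],
                    strainTrials = if (family == "binomial_od") trials[sIdx])
}

#' Wald Z-score matrix of all strains against the wild-type reference
#'
#' Applies [normalizeCV()] and then fits [fitStrainEffect()] for every
#' non-reference strain and every parameter. Parameters whose fit fails or
#' does not converge for any strain, or that contain missing values, are
#' dropped with a logged count.
#'
#' @param table a \linkS4class{MorphoSet}.
#' @param reference group label of the reference cultures (default
#'   \code{"wildtype"}); at least 2 reference cultures are required.
#' @param span,scope passed to [normalizeCV()].
#' @return A \linkS4class{ZScoreMatrix} (strains x parameters).
#' @export
zscoreMatrix <- function(table, reference = "wildtype", span = 0.4,
                         scope = "global") {
    cd <- SummarizedExperiment::colData(table)
    refIdx <- cd$group == reference
    if (sum(refIdx) < 2)
        stop("reference group '", reference, "' absent or has < 2 cultures")
    rd <- SummarizedExperiment::rowData(table)
    if (any(rd$family == "gaussian_cv"))
        table <- normalizeCV(table, span = span, scope = scope,
                             reference = reference)
    vals <- SummarizedExperiment::assay(table, "value")
    trials <- SummarizedExperiment::assay(table, "trials")
    strains <- unique(cd$strain_id[!refIdx])

    z <- matrix(NA_real_, length(strains), nrow(vals),
                dimnames = list(strains, rownames(vals)))
    for (i in seq_len(nrow(vals))) {
        if (anyNA(vals[i, ])) next  # dropped below
        for (s in strains) {
            fit <- .fitRow(vals[i, ], trials[i, ], cd$strain_id, refIdx, s,
                           rd$family[i], rd$link[i])
            z[s, i] <- if (isTRUE(fit$converged)) fit$z else NA_real_
        }
    }
    dropped <- colnames(z)[apply(z, 2, anyNA)]
    if (length(dropped))
        message(length(dropped), " parameter(s) dropped (failed fit or ",
                "missing value): ", paste(utils::head(dropped, 5),
                                          collapse = ", "),
                if (length(dropped) > 5) ", ...")
    z <- z[, setdiff(colnames(z), dropped), drop = FALSE]
    methods::new("ZScoreMatrix", z = z, reference = reference,
                 dropped = dropped,
                 provenance = rlang::hash(as.data.frame(rd)))
}

#' Leave-one-out Z-scores of the reference replicates
#'
#' Treats each reference culture in turn as a single-culture pseudo-strain
#' against the remaining reference cultures, giving the null-distributed
#' replicate Z-score matrix used for the Mahalanobis covariance and for the
#' null PCA that collapses correlated parameters.
#'
#' @inheritParams zscoreMatrix
#' @return A \linkS4class{ZScoreMatrix} with one row per reference culture.
#' @export
referenceZMatrix <- function(table, reference = "wildtype", span = 0.4,
                             scope = "global") {
    cd <- SummarizedExperiment::colData(table)
    refIdx <- which(cd$group == reference)
    if (length(refIdx) < 3)
        stop("need >= 3 reference cultures for leave-one-out Z-scores")
    rd <- SummarizedExperiment::rowData(table)
    if (any(rd$family == "gaussian_cv"))
        table <- normalizeCV(table, span = span, scope = scope,
                             reference = reference)
    vals <- SummarizedExperiment::assay(table, "value")
    trials <- SummarizedExperiment::assay(table, "trials")

    z <- matrix(NA_real_, length(refIdx), nrow(vals),
                dimnames = list(colnames(table)[refIdx], rownames(vals)))
    for (i in seq_len(nrow(vals))) {
        if (anyNA(vals[i, refIdx])) next
        for (k in seq_along(refIdx)) {
            own <- refIdx[k]; rest <- setdiff(refIdx, own)
            fit <- fitStrainEffect(vals[i, rest], vals[i, own],
                rd$family[i], rd$link[i],
                refTrials = if (rd$family[i] == "binomial_od") trials[i, rest],
                strainTrials = if (rd$family[i] == "binomial_od") trials[i, own])
            z[k, i] <- if (isTRUE(fit$converged)) fit$z else NA_real_
        }
    }
    dropped <- colnames(z)[apply(z, 2, anyNA)]
    z <- z[, setdiff(colnames(z), dropped), drop = FALSE]
    methods::new("ZScoreMatrix", z = z, reference = reference,
                 dropped = dropped,
                 provenance = rlang::hash(as.data.frame(rd)))
}
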