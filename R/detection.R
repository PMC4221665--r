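## One-sample per-PC detection of deletion strains beyond natural variation,
## with Bonferroni family-wise error control.

#' Natural-strain standard deviation per principal component
#'
#' Per component, \eqn{sd = \sqrt{\sum_i (score_i - center)^2 / n}}: the
#' natural scores are centered by the wild-type reference mean (an external,
#' known center), so the divisor is n, the unbiased convention for a known
#' center.
#'
#' @param naturalScores matrix of natural-strain scores (strains x
#'   components); >= 2 rows.
#' @param center numeric vector, the reference score per component
#'   (recycled if scalar).
#' @return named numeric vector of per-component standard deviations.
#' @export
naturalVariancePerPC <- function(naturalScores, center = 0) {
    naturalScores <- as.matrix(naturalScores)
    if (nrow(naturalScores) < 2) stop("need >= 2 natural strains")
    center <- rep_len(center, ncol(naturalScores))
    s <- sqrt(colMeans(sweep(naturalScores, 2, center)^2))
    if (any(s == 0))
        stop("degenerate component with zero natural variance: ",
             paste(colnames(naturalScores)[s == 0], collapse = ", "))
    names(s) <- colnames(naturalScores)
    s
}

#' Detect deletion strains beyond the variation of natural strains
#'
#' For each deletion strain and each requested component, the statistic
#' \eqn{z = (score - center) / sd_{natural}} is referred two-sidedly to a
#' null distribution, with Bonferroni correction over
#' \eqn{m = n_{strains} \times n_{components}} tests. A strain significant
#' in at least one component is called heteroclite.
#'
#' The default null distribution is Student t with \code{df = n} natural
#' strains: with the natural sd estimated from n strains about a known
#' external center, \eqn{(score-center)/\hat{sd}} is exactly
#' \eqn{t_n}-distributed under the null, so the Bonferroni bound holds at
#' the nominal level. \code{nullDist = "normal"} refers the statistic to the
#' standard normal instead; this ignores the sd estimation noise and
#' inflates the family-wise error several-fold at these extreme per-test
#' levels (see the package vignette), but is retained because it is the
#' classical one-sample normal test.
#'
#' @param deletionScores matrix of deletion-strain scores (strains x
#'   components, component columns named like the natural ones).
#' @param naturalScores matrix of natural-strain scores.
#' @param center reference (wild-type) score per component.
#' @param components component indices to test (default 1:4).
#' @param alpha nominal family-wise level (default 0.05).
#' @param nullDist \code{"t"} (default, calibrated) or \code{"normal"}.
#' @param mTests Bonferroni denominator; defaults to
#'   \code{nrow(deletionScores) * length(components)}. Supply the original
#'   m when re-running the test on a different strain panel (robustness
#'   re-runs) or on a component subset, so the per-test threshold stays
#'   fixed.
#' @return list with \code{results} (data.frame strain x component:
#'   \code{z_stat}, \code{p_two_sided}, \code{significant}),
#'   \code{heteroclites} (strain ids significant in >= 1 component),
#'   \code{m_tests}, \code{alpha}, \code{per_component} (detected counts),
#'   \code{sd_natural}.
#' @export
detectHeteroclites <- function(deletionScores, naturalScores, center = 0,
                               components = 1:4, alpha = 0.05,
                               nullDist = c("t", "normal"),
                               mTests = NULL) {
    nullDist <- match.arg(nullDist)
    deletionScores <- as.matrix(deletionScores)
    naturalScores <- as.matrix(naturalScores)
    if (max(components) > ncol(naturalScores) ||
        max(components) > ncol(deletionScores))
        stop("requested components not available in the score matrices")
    center <- rep_len(center, ncol(naturalScores))

    nat <- naturalScores[, components, drop = FALSE]
    del <- deletionScores[, components, drop = FALSE]
    ctr <- center[components]
    sdNat <- naturalVariancePerPC(nat, ctr)
    m <- if (is.null(mTests)) nrow(del) * length(components) else mTests
    if (nrow(del) == 0)
        return(list(results = data.frame(strain_id = character(0),
                                         component = integer(0),
                                         z_stat = numeric(0),
                                         p_two_sided = numeric(0),
                                         significant = logical(0)),
                    heteroclites = character(0), m_tests = 0L,
                    alpha = alpha, per_component = integer(0),
                    sd_natural = sdNat))

    z <- sweep(sweep(del, 2, ctr), 2, sdNat, "/")
    p <- if (nullDist == "t") 2 * stats::pt(-abs(z), df = nrow(nat))
         else 2 * stats::pnorm(-abs(z))
    sig <- p < alpha / m

    results <- data.frame(
        strain_id = rep(rownames(del), length(components)),
        component = rep(components, each = nrow(del)),
        z_stat = as.numeric(z), p_two_sided = as.numeric(p),
        significant = as.logical(sig), row.names = NULL)
    perComp <- colSums(sig)
    names(perComp) <- paste0("PC", components)
    list(results = results,
         heteroclites = sort(unique(results$strain_id[results$significant])),
         m_tests = m, alpha = alpha, per_component = perComp,
         sd_natural = sdNat)
}

#' Per-component detection counts and cross-component overlap
#'
#' @param detection result of [detectHeteroclites()].
#' @return list with \code{per_component} counts, \code{exactly_one} and
#'   \code{two_or_more} strain counts, and \code{union_size}.
#' @export
overlapSummary <- function(detection) {
    res <- detection$results
    if (is.null(res)) stop("empty detection result")
    hits <- res[res$significant, , drop = FALSE]
    perStrain <- table(hits$strain_id)
    list(per_component = detection$per_component,
         exactly_one = sum(perStrain == 1),
         two_or_more = sum(perStrain >= 2),
         union_size = length(detection$heteroclites))
}

#' Choose components by cumulative explained-variance ratio
#'
#' Returns the smallest prefix of components whose cumulative proportion of
#' explained variance reaches \code{targetRatio} (default 0.6, the level
#' reached by the first four components in the assay this package models).
#'
#' @param pcm a \linkS4class{PCModel}.
#' @param targetRatio cumulative proportion to reach (default 0.6).
#' @return integer vector of component indices.
#' @export
componentsByRatio <- function(pcm, targetRatio = 0.6) {
    cum <- cumsum(propVarExplained(pcm))
    seq_len(which(cum >= targetRatio)[1])
}
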