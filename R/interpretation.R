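## PC interpretation: which parameters characterize each component, and
## collapsing of correlated parameters via a PCA on null-distributed
## wild-type replicate Z-scores.

#' Significant parameter loadings per principal component
#'
#' The loading of a parameter on a component is the Pearson correlation
#' between the parameter's Z-score column and the component's score column;
#' its p-value comes from the correlation test. A parameter passes for a
#' component when \code{|loading| > loadingThreshold} and
#' \code{p < pThreshold}.
#'
#' @param z \linkS4class{ZScoreMatrix} (or matrix) the PCA was fit on.
#' @param pcm the \linkS4class{PCModel}.
#' @param components components to analyze (default 1:4).
#' @param loadingThreshold default 0.6.
#' @param pThreshold default 1.95e-3 (a Bonferroni-corrected level).
#' @return data.frame with \code{param_id}, \code{component},
#'   \code{loading}, \code{p_value}, \code{passes}; constant parameter
#'   columns are skipped with a message.
#' @export
significantLoadings <- function(z, pcm, components = 1:4,
                                loadingThreshold = 0.6,
                                pThreshold = 1.95e-3) {
    m <- .asZ(z)
    sc <- pcScores(pcm)
    stopifnot(max(components) <= ncol(sc), nrow(m) == nrow(sc))
    skipped <- character(0)
    rows <- list()
    for (p in colnames(m)) {
        x <- m[, p]
        if (stats::var(x) == 0) { skipped <- c(skipped, p); next }
        for (k in components) {
            ct <- stats::cor.test(x, sc[, k])
            rows[[length(rows) + 1L]] <- data.frame(
                param_id = p, component = k,
                loading = unname(ct$estimate), p_value = ct$p.value)
        }
    }
    if (length(skipped))
        message(length(skipped), " constant parameter(s) skipped")
    calls <- do.call(rbind, rows)
    calls$passes <- abs(calls$loading) > loadingThreshold &
        calls$p_value < pThreshold
    rownames(calls) <- NULL
    calls
}

#' Collapse correlated parameters using null-distributed replicates
#'
#' Parameters that pass the loading rule in the primary analysis may be
#' mutually correlated even in wild-type replicates, in which case they
#' measure the same underlying feature. This runs a second PCA on the
#' replicate (null) Z-score matrix, applies the same loading-significance
#' rule there, and groups passing parameters that load on a common null
#' component; each group's representative is the member with the largest
#' absolute loading on its primary-analysis component (ties broken by
#' ascending parameter id). Parameters not attached to any null component
#' stay as singleton groups.
#'
#' @param calls data.frame from [significantLoadings()] (only rows with
#'   \code{passes} are used).
#' @param nullZ \linkS4class{ZScoreMatrix} (or matrix) of wild-type
#'   replicate Z-scores; >= 3 rows.
#' @param loadingThreshold,pThreshold the rule applied to the null PCA
#'   loadings (defaults as in the primary analysis).
#' @return list with \code{groups} (named list of parameter-id vectors),
#'   \code{representatives} (one id per group) and \code{table}
#'   (data.frame param_id, group, representative flag).
#' @export
representativeParameters <- function(calls, nullZ,
                                     loadingThreshold = 0.6,
                                     pThreshold = 1.95e-3) {
    passing <- calls[calls$passes, , drop = FALSE]
    if (nrow(passing) == 0) stop("no passing loading calls")
    m <- .asZ(nullZ)
    if (nrow(m) < 3) stop("need >= 3 null replicates")
    params <- sort(unique(passing$param_id))
    params <- intersect(params, colnames(m))

    npc <- pcaZ(m[, params, drop = FALSE])
    nsc <- pcScores(npc)
    ## best passing null component per parameter
    assign <- setNames(rep(NA_integer_, length(params)), params)
    bestLoad <- setNames(rep(0, length(params)), params)
    for (p in params) {
        for (k in seq_len(ncol(nsc))) {
            if (stats::var(m[, p]) == 0) next
            ct <- stats::cor.test(m[, p], nsc[, k])
            if (abs(ct$estimate) > loadingThreshold &&
                ct$p.value < pThreshold &&
                abs(ct$estimate) > abs(bestLoad[p])) {
                assign[p] <- k
                bestLoad[p] <- ct$estimate
            }
        }
    }
    groupKey <- ifelse(is.na(assign), paste0("singleton_", params),
                       paste0("nullPC", assign))
    groups <- split(params, groupKey)

    primLoad <- vapply(params, function(p)
        max(abs(passing$loading[passing$param_id == p])), numeric(1))
    reps <- vapply(groups, function(g)
        g[order(-primLoad[g], g)][1], character(1))
    tab <- data.frame(param_id = params,
                      group = groupKey,
                      representative = params %in% reps,
                      row.names = NULL)
    list(groups = groups, representatives = unname(reps), table = tab)
}
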