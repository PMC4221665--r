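## GO-level association of deletion morphology with PC scores (nested-model
## MANOVA), hierarchical clustering of GO gene sets, and the auxiliary
## Mann-Whitney group comparisons and genetic-interaction counts.

#' Filter GO sets by focal-gene hits and genome-wide specificity
#'
#' Keeps gene-ontology sets annotated to fewer than \code{maxGenome} genes
#' genome-wide and hitting at least \code{minHits} of the focal genes (the
#' detected deletion strains).
#'
#' @param gos list of GO sets as returned by [readGmt()].
#' @param focalGenes character vector of focal gene/strain identifiers.
#' @param minHits minimum focal genes annotated (default 3).
#' @param maxGenome exclusive upper bound on genome-wide annotation count
#'   (default 100).
#' @return the filtered list, with an added \code{n_hits} element per set.
#' @export
selectGOs <- function(gos, focalGenes, minHits = 3, maxGenome = 100) {
    kept <- lapply(gos, function(g) {
        g$n_hits <- length(intersect(g$genes, focalGenes))
        g
    })
    Filter(function(g) g$genome_count < maxGenome && g$n_hits >= minHits,
           kept)
}

#' Nested-model MANOVA of PC scores on GO membership
#'
#' Fits the multivariate linear models \code{Y ~ s} (null: morphology is
#' explained by strain background only) and \code{Y ~ s + x} (alternative:
#' plus GO membership), where \code{Y} holds the PC scores (by convention
#' PC1, PC2 and PC4), \code{s} is the background factor and \code{x} the
#' 0/1 GO-membership indicator, and compares them with a multivariate
#' F-approximation (Pillai trace by default).
#'
#' @param scores matrix of PC scores, strains x components.
#' @param s background factor, one level per strain background (e.g.
#'   natural vs laboratory).
#' @param x 0/1 GO-membership indicator per strain; at least 2 strains with
#'   \code{x = 1}.
#' @param test \code{"Pillai"} (default) or \code{"Wilks"}.
#' @return list with \code{statistic}, \code{F_approx}, \code{p_value},
#'   \code{n_strains_used}, \code{test}.
#' @export
manovaGO <- function(scores, s, x, test = c("Pillai", "Wilks")) {
    test <- match.arg(test)
    Y <- as.matrix(scores)
    s <- as.factor(s)
    x <- as.numeric(x)
    stopifnot(nrow(Y) == length(s), nrow(Y) == length(x))
    if (length(unique(x)) < 2)
        stop("GO indistinguishable from background: all x identical")
    if (sum(x == 1) < 2) stop("need >= 2 strains with x = 1")

    if (ncol(Y) == 1) {
        y <- Y[, 1]
        fit0 <- stats::lm(y ~ s)
        fit1 <- stats::lm(y ~ s + x)
        an <- stats::anova(fit0, fit1)
        return(list(statistic = an$F[2], F_approx = an$F[2],
                    p_value = an$`Pr(>F)`[2], n_strains_used = nrow(Y),
                    test = "F"))
    }
    fit0 <- stats::lm(Y ~ s)
    fit1 <- stats::lm(Y ~ s + x)
    an <- stats::anova(fit1, fit0, test = test)
    i <- nrow(an)  # row of the model difference
    list(statistic = an[i, test], F_approx = an[i, "approx F"],
         p_value = an[i, "Pr(>F)"], n_strains_used = nrow(Y), test = test)
}

#' MANOVA over a list of GO sets with Bonferroni calls
#'
#' Runs [manovaGO()] for each selected GO set. Per the assay's convention,
#' each GO's model uses the natural strains and the wild-type reference
#' (x = 0) together with the deletion strains annotated to the GO (x = 1);
#' unannotated deletion strains are excluded unless
#' \code{includeUnannotated} is TRUE (then included with x = 0).
#'
#' @param scores matrix of PC scores for all strains (rownames = strain or
#'   gene ids).
#' @param groups named character vector mapping each score row to
#'   \code{wildtype}, \code{natural} or \code{deletion}.
#' @param gos filtered GO list from [selectGOs()].
#' @param alpha nominal level for the Bonferroni call over the tested GOs
#'   (default 0.05).
#' @param includeUnannotated include unannotated deletion strains with
#'   x = 0 (default FALSE).
#' @param test passed to [manovaGO()].
#' @return data.frame with one row per GO: statistic, F, p, Bonferroni-
#'   adjusted significance call, and strain counts.
#' @export
manovaGOTable <- function(scores, groups, gos, alpha = 0.05,
                          includeUnannotated = FALSE, test = "Pillai") {
    scores <- as.matrix(scores)
    groups <- groups[rownames(scores)]
    rows <- lapply(gos, function(g) {
        isDel <- groups == "deletion"
        inGo <- rownames(scores) %in% g$genes
        keep <- !isDel | inGo | includeUnannotated
        Y <- scores[keep, , drop = FALSE]
        s <- ifelse(groups[keep] == "natural", "natural", "by_background")
        x <- as.numeric(isDel[keep] & inGo[keep])
        res <- manovaGO(Y, s, x, test = test)
        data.frame(go_id = g$go_id, n_hits = sum(x),
                   statistic = res$statistic, F_approx = res$F_approx,
                   p_value = res$p_value,
                   n_strains_used = res$n_strains_used)
    })
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    out$significant <- out$p_value < alpha / nrow(out)
    out
}

## pairwise set distance
.setDistance <- function(a, b, method) {
    inter <- length(intersect(a, b))
    switch(method,
        jaccard = 1 - inter / length(union(a, b)),
        dice = 1 - 2 * inter / (length(a) + length(b)))
}

#' Complete-linkage clustering of GO gene sets
#'
#' Pairwise distance is 1 - Jaccard index of the annotated gene sets
#' (optionally Dice); clustering is agglomerative with complete linkage.
#'
#' @param gos list of GO sets (>= 2, unique ids).
#' @param method \code{"jaccard"} (default) or \code{"dice"}.
#' @return an \code{hclust} object (merge order and heights).
#' @export
clusterGOs <- function(gos, method = c("jaccard", "dice")) {
    method <- match.arg(method)
    ids <- vapply(gos, `[[`, "", "go_id")
    if (anyDuplicated(ids)) stop("duplicate go_id")
    if (length(gos) < 2) stop("need >= 2 GO sets")
    n <- length(gos)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        d[i, j] <- d[j, i] <- .setDistance(gos[[i]]$genes, gos[[j]]$genes,
                                           method)
    stats::hclust(stats::as.dist(d), method = "complete")
}

#' Mann-Whitney U test with continuity and tie corrections
#'
#' Wraps \code{stats::wilcox.test}: the exact enumeration p-value is used
#' when both groups have at most 8 observations and there are no ties;
#' otherwise the normal approximation with continuity and tie corrections.
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @return list with \code{U} (statistic for groupA) and \code{p_two_sided}.
#' @export
mannWhitney <- function(groupA, groupB) {
    stopifnot(length(groupA) > 0, length(groupB) > 0)
    ties <- anyDuplicated(c(groupA, groupB)) > 0
    exact <- length(groupA) <= 8 && length(groupB) <= 8 && !ties
    wt <- suppressWarnings(stats::wilcox.test(groupA, groupB,
                                              exact = exact,
                                              correct = TRUE))
    list(U = unname(wt$statistic), p_two_sided = wt$p.value,
         exact = exact)
}

#' Count significant genetic interactions per gene
#'
#' A partner counts when (epsilon < \code{epsNeg} and p < \code{pCut}) or
#' (epsilon > \code{epsPos} and p < \code{pCut}); epsilon values between
#' the two cutoffs never count.
#'
#' @param records data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{epsilon}, \code{p_value}.
#' @param genes genes to count interactions for.
#' @param epsNeg,epsPos,pCut stringent cutoffs (defaults -0.12, 0.16, 0.05).
#' @return named integer vector of interaction counts.
#' @export
interactionCounts <- function(records, genes, epsNeg = -0.12,
                              epsPos = 0.16, pCut = 0.05) {
    counts <- setNames(integer(length(genes)), genes)
    if (is.null(records) || nrow(records) == 0) return(counts)
    sig <- records$p_value < pCut &
        (records$epsilon < epsNeg | records$epsilon > epsPos)
    rec <- records[sig, , drop = FALSE]
    for (g in genes)
        counts[g] <- sum(rec$gene_a == g) + sum(rec$gene_b == g)
    counts
}
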