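## Mahalanobis ranking of strains against the wild-type replicate center and
## representative-strain selection (top distance + PC-space edge).

.asZ <- function(x) if (methods::is(x, "ZScoreMatrix")) zMatrix(x) else as.matrix(x)

#' Mahalanobis distance of every strain from the wild-type center
#'
#' The center is the column mean of the reference replicate Z-scores and the
#' covariance is estimated from the same replicates. Because the number of
#' parameters usually far exceeds the number of reference replicates, the
#' default covariance is the diagonal of the sample covariance (floored at
#' \code{floor}); linear shrinkage of the full covariance toward its
#' diagonal, or the full sample covariance, are available when the reference
#' panel is large enough.
#'
#' @param z \linkS4class{ZScoreMatrix} (or matrix) of the strains to rank.
#' @param referenceZ \linkS4class{ZScoreMatrix} (or matrix) of reference
#'   replicates; at least 2 rows.
#' @param method covariance estimator: \code{"diagonal"} (default),
#'   \code{"shrinkage"} or \code{"full"}.
#' @param shrink shrinkage weight toward the diagonal for
#'   \code{method = "shrinkage"} (0..1, default 0.5).
#' @param floor lower bound on the diagonal variances (default 1e-6).
#' @return data.frame with \code{strain_id}, \code{distance} and dense
#'   \code{rank} (1 = most distant; ties broken by ascending strain id).
#' @export
mahalanobisDistances <- function(z, referenceZ,
                                 method = c("diagonal", "shrinkage", "full"),
                                 shrink = 0.5, floor = 1e-6) {
    method <- match.arg(method)
    z <- .asZ(z); ref <- .asZ(referenceZ)
    common <- intersect(colnames(z), colnames(ref))
    if (length(common) < 1) stop("no shared parameters")
    z <- z[, common, drop = FALSE]; ref <- ref[, common, drop = FALSE]
    if (nrow(ref) < 2) stop("need >= 2 reference replicate rows")

    center <- colMeans(ref)
    sigma <- switch(method,
        diagonal = diag(pmax(apply(ref, 2, stats::var), floor),
                        ncol(ref)),
        full = stats::cov(ref),
        shrinkage = {
            S <- stats::cov(ref)
            (1 - shrink) * S + shrink * diag(pmax(diag(S), floor))
        })
    ok <- tryCatch({ solve(sigma); TRUE }, error = function(e) FALSE)
    if (!ok)
        stop("reference covariance is not invertible (condition number ",
             format(kappa(sigma), digits = 3),
             "); use method = 'diagonal' or 'shrinkage'")
    d <- sqrt(stats::mahalanobis(z, center, sigma))
    ord <- order(-d, rownames(z))
    rank <- integer(length(d)); rank[ord] <- seq_along(d)
    data.frame(strain_id = rownames(z), distance = as.numeric(d),
               rank = rank, row.names = NULL)
}

#' Select representative strains by distance and PC-space edge
#'
#' The \code{kTop} strains with the highest Mahalanobis distance are
#' selected first. Among the remainder, PCA scores over the first
#' \code{nPcs} components are standardized per component, and the
#' \code{kEdge} strains maximizing their largest absolute standardized score
#' are added, capturing strains at the edge of the PC space that a global
#' distance misses.
#'
#' @param distances data.frame from [mahalanobisDistances()].
#' @param z \linkS4class{ZScoreMatrix} (or matrix) the distances were
#'   computed on.
#' @param kTop strains selected by distance (default 100).
#' @param kEdge strains selected at the PC edge (default 20).
#' @param nPcs components scanned for edge strains (default 20; clipped
#'   with a warning when fewer are available).
#' @return data.frame with \code{strain_id}, \code{distance}, \code{rank}
#'   and \code{reason} (\code{top_distance}, \code{pc_edge} or \code{none})
#'   for all strains; selected strains are those with reason != "none".
#' @export
selectStrains <- function(distances, z, kTop = 100, kEdge = 20, nPcs = 20) {
    z <- .asZ(z)
    stopifnot(all(distances$strain_id %in% rownames(z)))
    if (kTop + kEdge > nrow(distances))
        stop("kTop + kEdge exceeds the number of strains")
    ord <- order(-distances$distance, distances$strain_id)
    reason <- setNames(rep("none", nrow(distances)), distances$strain_id)
    top <- distances$strain_id[ord][seq_len(kTop)]
    reason[top] <- "top_distance"

    if (kEdge > 0) {
        pcm <- pcaZ(z)
        sc <- pcScores(pcm)
        if (nPcs > ncol(sc)) {
            warning("nPcs clipped from ", nPcs, " to ", ncol(sc))
            nPcs <- ncol(sc)
        }
        sc <- sc[, seq_len(nPcs), drop = FALSE]
        sdc <- apply(sc, 2, stats::sd)
        edgeStat <- apply(abs(sweep(sc, 2, sdc, "/")), 1, max)
        rest <- setdiff(distances$strain_id, top)
        eo <- rest[order(-edgeStat[rest], rest)]
        reason[eo[seq_len(kEdge)]] <- "pc_edge"
    }
    out <- distances
    out$reason <- unname(reason[out$strain_id])
    out[order(out$rank), ]
}
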