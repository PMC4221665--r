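## Per-trait variance conventions, PCA of the Z-score covariance, bivariate
## equiprobability density ellipses, and the population-broadness ratio.

#' Per-trait variance under the degrees-of-freedom conventions of the assay
#'
#' Three centering conventions are used when comparing populations of
#' different sizes: \code{own_mean} centers by the sample mean (divisor
#' n - 1); \code{per_subgroup_mean} pools sums of squares about each
#' subgroup's own mean (divisor \eqn{\sum (n_g - 1)}, e.g. 4 for two
#' triplicates); \code{reference_mean} centers by an externally supplied
#' reference value (divisor n, the unbiased choice for a known center).
#'
#' @param values numeric vector of Z-values (NAs removed).
#' @param centering one of \code{own_mean}, \code{per_subgroup_mean},
#'   \code{reference_mean}.
#' @param groups subgroup labels, required for \code{per_subgroup_mean}.
#' @param center external center, required for \code{reference_mean}.
#' @return list with \code{variance} and \code{df_used}.
#' @export
perTraitVariance <- function(values,
                             centering = c("own_mean", "per_subgroup_mean",
                                           "reference_mean"),
                             groups = NULL, center = NULL) {
    centering <- match.arg(centering)
    keep <- !is.na(values)
    values <- values[keep]
    if (length(values) < 2) stop("need >= 2 values")
    switch(centering,
        own_mean = list(variance = sum((values - mean(values))^2) /
                            (length(values) - 1),
                        df_used = length(values) - 1L),
        per_subgroup_mean = {
            if (is.null(groups)) stop("groups required for per_subgroup_mean")
            groups <- groups[keep]
            ns <- table(groups)
            if (any(ns == 0)) stop("empty subgroup")
            ss <- sum(tapply(values, groups,
                             function(v) sum((v - mean(v))^2)))
            df <- sum(ns - 1L)
            if (df < 1) stop("no residual degrees of freedom")
            list(variance = ss / df, df_used = as.integer(df))
        },
        reference_mean = {
            if (is.null(center)) stop("center required for reference_mean")
            list(variance = sum((values - center)^2) / length(values),
                 df_used = length(values))
        })
}

#' Per-parameter variance ratio between two populations
#'
#' For every parameter shared by the two Z-score matrices, computes
#' var(A)/var(B) with own-mean centering and divisor n - 1 per group (109
#' for a 110-strain panel), and counts the parameters with ratio strictly
#' greater than 1. Parameters with zero variance in B are flagged infinite
#' and excluded from the count.
#'
#' @param zA,zB \linkS4class{ZScoreMatrix} (or matrix) of the two
#'   populations (numerator A, denominator B).
#' @return list with \code{ratio} (named vector), \code{exceed_count},
#'   \code{n_shared}, \code{excluded} (ids with zero denominator).
#' @export
varianceRatioProfile <- function(zA, zB) {
    a <- .asZ(zA); b <- .asZ(zB)
    common <- intersect(colnames(a), colnames(b))
    if (length(common) < 1) stop("no shared parameters")
    va <- apply(a[, common, drop = FALSE], 2, stats::var, na.rm = TRUE)
    vb <- apply(b[, common, drop = FALSE], 2, stats::var, na.rm = TRUE)
    ratio <- va / vb
    excluded <- common[vb == 0]
    if (length(excluded))
        message(length(excluded),
                " parameter(s) with zero denominator variance excluded")
    list(ratio = ratio,
         exceed_count = sum(ratio[vb > 0] > 1),
         n_shared = length(common), excluded = excluded)
}

#' PCA of the Z-score variance-covariance matrix
#'
#' Column-centered, unscaled principal-component analysis (the covariance,
#' not correlation, convention: Z-scores are already variance-standardized
#' by construction).
#'
#' @param z \linkS4class{ZScoreMatrix} or plain matrix (strains x
#'   parameters).
#' @return A \linkS4class{PCModel}.
#' @export
pcaZ <- function(z) {
    m <- .asZ(z)
    if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 strains and >= 2 parameters")
    if (all(apply(m, 2, stats::var) == 0)) stop("constant matrix")
    pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    methods::new("PCModel", loadings = pr$rotation, scores = pr$x,
                 varExplained = pr$sdev^2, center = pr$center)
}

#' Project new strain profiles onto an existing PC model
#'
#' @param pcm a \linkS4class{PCModel}.
#' @param z matrix (or \linkS4class{ZScoreMatrix}) with the model's
#'   parameters in columns; a zero vector projects the wild-type reference
#'   itself (its Z-score against itself is identically zero).
#' @return score matrix, rows matching \code{z}.
#' @export
projectScores <- function(pcm, z) {
    m <- .asZ(z)
    m <- m[, names(pcm@center), drop = FALSE]
    sweep(m, 2, pcm@center) %*% pcLoadings(pcm)
}

## bivariate normal density, closed form
.dmvn2 <- function(x, y, mean, sigma) {
    si <- solve(sigma)
    dx <- x - mean[1]; dy <- y - mean[2]
    q <- si[1, 1] * dx^2 + 2 * si[1, 2] * dx * dy + si[2, 2] * dy^2
    exp(-q / 2) / (2 * pi * sqrt(det(sigma)))
}

#' Equiprobability density ellipse of a 2-D score cloud
#'
#' Fits a bivariate normal to the points (or an equal-weight two-component
#' Gaussian mixture when a second point set is given), evaluates the density
#' on a \code{gridSize} x \code{gridSize} grid spanning the data range plus
#' 3 marginal standard deviations, and picks the density level whose
#' super-level set encloses \code{massLevel} of the fitted probability mass.
#'
#' @param points n x 2 matrix of scores (>= 3 rows).
#' @param massLevel probability mass the contour encloses (default 0.95).
#' @param mixture optional second n x 2 point set; the fit becomes an
#'   equal-weight mixture of the two component normals.
#' @param gridSize grid resolution per axis (default 200).
#' @param weights mixture weights (default equal).
#' @return list of class \code{ellipseSpec}: \code{mean}, \code{cov}
#'   (moments of the fitted model), \code{mass_level}, \code{level}
#'   (density at the contour), \code{area} (area of the super-level set),
#'   \code{grid} (list \code{x}, \code{y}, \code{density}).
#' @export
equiprobabilityEllipse <- function(points, massLevel = 0.95, mixture = NULL,
                                   gridSize = 200, weights = c(0.5, 0.5)) {
    points <- as.matrix(points)
    stopifnot(ncol(points) == 2, nrow(points) >= 3)
    comps <- list(list(mean = colMeans(points), sigma = stats::cov(points)))
    if (!is.null(mixture)) {
        mixture <- as.matrix(mixture)
        stopifnot(ncol(mixture) == 2, nrow(mixture) >= 3)
        comps[[2]] <- list(mean = colMeans(mixture),
                           sigma = stats::cov(mixture))
        weights <- weights / sum(weights)
    } else weights <- 1
    for (cmp in comps) {
        ev <- eigen(cmp$sigma, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) <= max(ev) * 1e-10)
            stop("degenerate (collinear) points: covariance is singular")
    }
    ## moments of the fitted (possibly mixture) model
    mu <- Reduce(`+`, Map(function(c, w) w * c$mean, comps, weights))
    sig <- Reduce(`+`, Map(function(c, w)
        w * (c$sigma + tcrossprod(c$mean - mu)), comps, weights))

    all <- rbind(points, if (!is.null(mixture)) mixture)
    sdm <- apply(all, 2, stats::sd)
    gx <- seq(min(all[, 1]) - 3 * sdm[1], max(all[, 1]) + 3 * sdm[1],
              length.out = gridSize)
    gy <- seq(min(all[, 2]) - 3 * sdm[2], max(all[, 2]) + 3 * sdm[2],
              length.out = gridSize)
    dens <- matrix(0, gridSize, gridSize)
    for (k in seq_along(comps))
        dens <- dens + weights[k] *
            outer(gx, gy, .dmvn2, mean = comps[[k]]$mean,
                  sigma = comps[[k]]$sigma)
    cellArea <- diff(gx[1:2]) * diff(gy[1:2])
    ds <- sort(as.numeric(dens), decreasing = TRUE)
    cum <- cumsum(ds) * cellArea
    idx <- which(cum >= massLevel)[1]
    if (is.na(idx)) idx <- length(ds)  # grid truncation: take all mass seen
    level <- ds[idx]
    structure(list(mean = mu, cov = sig, mass_level = massLevel,
                   level = level, area = idx * cellArea,
                   grid = list(x = gx, y = gy, density = dens)),
              class = "ellipseSpec")
}

#' Broadness ratio of two populations in a 2-D PC space
#'
#' The ratio of equiprobability-ellipse areas at a common mass level, which
#' for fitted normals reduces to \eqn{\sqrt{\det \Sigma_A / \det \Sigma_B}}.
#' Per-axis standard-deviation ratios are attached as an attribute.
#'
#' @param ellipseA,ellipseB \code{ellipseSpec} objects from
#'   [equiprobabilityEllipse()] over the same two components.
#' @return positive scalar; attribute \code{axis_sd_ratio} carries the two
#'   marginal sd ratios.
#' @export
broadnessRatio <- function(ellipseA, ellipseB) {
    stopifnot(inherits(ellipseA, "ellipseSpec"),
              inherits(ellipseB, "ellipseSpec"))
    if (!isTRUE(all.equal(ellipseA$mass_level, ellipseB$mass_level)))
        warning("ellipses use different mass levels")
    r <- sqrt(det(ellipseA$cov) / det(ellipseB$cov))
    attr(r, "axis_sd_ratio") <- sqrt(diag(ellipseA$cov) / diag(ellipseB$cov))
    r
}
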