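## End-to-end orchestration: simulate -> Z-scores -> selection -> variance /
## PCA -> detection -> interpretation -> GO MANOVA, under one seeded config.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the assay's
#' published design constants (Lowess span 0.4; selection quotas 100 + 20
#' over 20 PCs; components PC1-PC4 or the smallest prefix reaching 60\%
#' cumulative variance; nominal level 0.05; loading rule 0.6 /
#' 1.95e-3; 200 x 200 density grid). Unknown arguments are an error.
#'
#' @param seed root seed; the simulation seed derives from it.
#' @param sim a [simConfig()]; defaults to \code{simConfig(seed = seed)}.
#' @param span Lowess span for CV normalization.
#' @param kTop,kEdge,nPcs strain-selection quotas and PC window.
#' @param components PCs tested for heteroclite detection.
#' @param componentRule \code{"fixed"} uses \code{components};
#'   \code{"cumulative"} picks the smallest prefix reaching
#'   \code{cumulativeTarget}.
#' @param cumulativeTarget cumulative explained-variance target (0.6).
#' @param alpha nominal family-wise level.
#' @param nullDist reference distribution for detection (see
#'   [detectHeteroclites()]).
#' @param loadingThreshold,pThreshold loading-significance rule.
#' @param massLevel,gridSize equiprobability-ellipse settings.
#' @param gos optional GO list (from [readGmt()]) for the MANOVA stage.
#' @param minHits,maxGenome GO filters.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L, sim = NULL, span = 0.4, kTop = 100,
                           kEdge = 20, nPcs = 20, components = c(1, 2, 3, 4),
                           componentRule = c("fixed", "cumulative"),
                           cumulativeTarget = 0.6, alpha = 0.05,
                           nullDist = "t", loadingThreshold = 0.6,
                           pThreshold = 1.95e-3, massLevel = 0.95,
                           gridSize = 200, gos = NULL, minHits = 3,
                           maxGenome = 100) {
    componentRule <- match.arg(componentRule)
    if (is.null(sim)) sim <- simConfig(seed = seed)
    structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full analysis pipeline on simulated or supplied data
#'
#' Executes the stages in order: trait simulation, Z-score normalization,
#' leave-one-out reference Z-scores, Mahalanobis ranking (with
#' representative-strain selection when the quotas fit the panel), PCA,
#' per-trait variance-ratio profile, equiprobability ellipses and broadness
#' ratio on the first two tested components, heteroclite detection,
#' loading-based PC interpretation, and (when GO sets are supplied) the
#' GO MANOVA table. All outputs carry the configuration hash.
#'
#' @param config a [pipelineConfig()].
#' @param catalog a \linkS4class{ParameterCatalog}; default
#'   [buildDefaultCatalog()].
#' @param table optional \linkS4class{MorphoSet}; when supplied, the
#'   simulation stage is skipped and \code{config$sim} ignored.
#' @return list with the stage outputs (\code{z}, \code{referenceZ},
#'   \code{distances}, \code{selection}, \code{pca}, \code{varianceRatio},
#'   \code{ellipses}, \code{detection}, \code{loadings},
#'   \code{representatives}, \code{manova}) and a \code{summary} list
#'   (exceedance count, cumulative PC contribution, broadness ratio,
#'   heteroclite list with per-PC attribution, config hash).
#' @export
runPipeline <- function(config, catalog = buildDefaultCatalog(),
                        table = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    cfgHash <- rlang::hash(config)

    truthGroups <- NULL
    if (is.null(table)) {
        sim <- simulateMorphology(config$sim, catalog)
        table <- sim$table
        truthGroups <- sim$truth$groups
    }
    cd <- SummarizedExperiment::colData(table)

    z <- zscoreMatrix(table, span = config$span)
    refZ <- referenceZMatrix(table, span = config$span)
    distances <- mahalanobisDistances(z, refZ)

    selection <- NULL
    if (config$kTop + config$kEdge <= nrow(zMatrix(z))) {
        selection <- selectStrains(distances, z, kTop = config$kTop,
                                   kEdge = config$kEdge, nPcs = config$nPcs)
    } else {
        message("selection skipped: kTop + kEdge exceeds panel size")
    }

    pcm <- pcaZ(z)
    refScore <- projectScores(pcm,
        matrix(0, 1, ncol(zMatrix(z)),
               dimnames = list(z@reference, colnames(zMatrix(z)))))
    comps <- if (config$componentRule == "cumulative")
        componentsByRatio(pcm, config$cumulativeTarget)
    else config$components
    comps <- comps[comps <= ncol(pcScores(pcm))]

    groupOf <- cd$group[match(rownames(zMatrix(z)), cd$strain_id)]
    natRows <- groupOf == "natural"
    delRows <- groupOf == "deletion"
    sc <- pcScores(pcm)

    varianceRatio <- if (sum(delRows) >= 2 && sum(natRows) >= 2)
        varianceRatioProfile(zMatrix(z)[delRows, , drop = FALSE],
                             zMatrix(z)[natRows, , drop = FALSE])
    else NULL

    ellipses <- NULL; broadness <- NULL
    if (sum(natRows) >= 3 && sum(delRows) >= 3 && length(comps) >= 2) {
        two <- comps[1:2]
        eDel <- equiprobabilityEllipse(sc[delRows, two],
                                       massLevel = config$massLevel,
                                       gridSize = config$gridSize)
        eNat <- equiprobabilityEllipse(sc[natRows, two],
                                       massLevel = config$massLevel,
                                       gridSize = config$gridSize)
        broadness <- broadnessRatio(eDel, eNat)
        ellipses <- list(deletion = eDel, natural = eNat,
                         components = two)
    }

    detection <- detectHeteroclites(sc[delRows, , drop = FALSE],
                                    sc[natRows, , drop = FALSE],
                                    center = as.numeric(refScore),
                                    components = comps,
                                    alpha = config$alpha,
                                    nullDist = config$nullDist)

    loadings <- significantLoadings(z, pcm, components = comps,
                                    loadingThreshold = config$loadingThreshold,
                                    pThreshold = config$pThreshold)
    representatives <- if (any(loadings$passes))
        representativeParameters(loadings, refZ,
                                 loadingThreshold = config$loadingThreshold,
                                 pThreshold = config$pThreshold)
    else NULL

    manova <- NULL
    if (!is.null(config$gos) && length(detection$heteroclites)) {
        groups <- setNames(groupOf, rownames(sc))
        sel <- selectGOs(config$gos, detection$heteroclites,
                         minHits = config$minHits,
                         maxGenome = config$maxGenome)
        if (length(sel)) {
            Y <- sc[, comps, drop = FALSE]
            manova <- manovaGOTable(Y, groups, sel, alpha = config$alpha)
        }
    }

    hetAttr <- detection$results[detection$results$significant, , drop = FALSE]
    summary <- list(
        config_hash = cfgHash,
        n_parameters = ncol(zMatrix(z)),
        n_dropped = length(droppedParams(z)),
        components = comps,
        cumulative_contribution = cumsum(propVarExplained(pcm))[max(comps)],
        variance_ratio_exceedance =
            if (!is.null(varianceRatio)) varianceRatio$exceed_count else NA,
        broadness_ratio = if (!is.null(broadness)) as.numeric(broadness)
                          else NA,
        heteroclites = detection$heteroclites,
        heteroclite_attribution = hetAttr,
        per_component = detection$per_component,
        m_tests = detection$m_tests)

    list(table = table, z = z, referenceZ = refZ, distances = distances,
         selection = selection, pca = pcm, referenceScore = refScore,
         varianceRatio = varianceRatio, ellipses = ellipses,
         detection = detection, loadings = loadings,
         representatives = representatives, manova = manova,
         summary = summary, config = config, config_hash = cfgHash,
         groups = if (!is.null(truthGroups)) truthGroups else NULL)
}
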