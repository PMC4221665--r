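## Seeded generator of replicate-level trait tables with the statistical
## structure the analysis assumes: family-specific culture noise, strain
## effects drawn once per strain and correlated within parameter blocks,
## CV--mean coupling for the Lowess stage to remove, beta-binomial
## overdispersion, and planted outlier strains with known ground truth.

#' Simulation configuration
#'
#' Captures the study conditions emulated by [simulateMorphology()]: 40
#' wild-type reference cultures, 5 cultures per natural strain, a single
#' culture per deletion strain, and at least 200 cells scored per culture.
#' Strain effects are drawn once per strain on the link scale; deletion
#' strains receive a larger effect scale than natural strains so that the
#' deletion panel is the morphologically broader population.
#'
#' @param seed integer; fully determines the generated table.
#' @param nWildtypeReps wild-type reference cultures (default 40).
#' @param nNatural number of natural strains (default 36).
#' @param repsPerNatural cultures per natural strain (default 5).
#' @param nDeletion number of deletion strains (default 110).
#' @param repsPerDeletion cultures per deletion strain (default 1).
#' @param trialsPerCulture cells scored per culture for binomial traits
#'   (default 200).
#' @param naturalEffectSd link-scale standard deviation of natural-strain
#'   effects (default 0.2).
#' @param deletionEffectSd same for deletion strains (default 0.6; must be
#'   the larger scale for the deletion panel to be broader).
#' @param rho intra-culture correlation of the beta-binomial counts
#'   (default 0.05; 0 gives plain binomial sampling).
#' @param cvNoiseSd Gaussian noise of CV traits around their mean-coupled
#'   trend (default 0.05).
#' @param blockWeight share of strain-effect variance carried by the shared
#'   per-block latent factor (default 0.5); gives PCA its block structure.
#' @param gammaShape gamma shape of culture noise for gamma traits
#'   (default 100, i.e. ~10\% culture-to-culture CV).
#' @param betaPrecision precision of the beta culture noise (default 200).
#' @param planted list of planted outlier strains, each
#'   \code{list(strain_id =, direction = c(block = weight, ...), magnitude =)};
#'   the planted link-scale shift for a parameter in block \code{b} is
#'   \code{magnitude * naturalEffectSd * direction[b]}.
#' @return A list of class \code{SimulationConfig}.
#' @export
simConfig <- function(seed = 1L, nWildtypeReps = 40L, nNatural = 36L,
                      repsPerNatural = 5L, nDeletion = 110L,
                      repsPerDeletion = 1L, trialsPerCulture = 200L,
                      naturalEffectSd = 0.2, deletionEffectSd = 0.6,
                      rho = 0.05, cvNoiseSd = 0.05, blockWeight = 0.5,
                      gammaShape = 100, betaPrecision = 200,
                      planted = list()) {
    stopifnot(deletionEffectSd >= 0, naturalEffectSd >= 0,
              rho >= 0, rho < 1, blockWeight >= 0, blockWeight <= 1,
              trialsPerCulture >= 1)
    for (p in planted) {
        stopifnot(is.list(p), !is.null(p$strain_id), !is.null(p$direction),
                  !is.null(p$magnitude))
        if (p$magnitude < 0) stop("planted magnitude must be nonnegative")
    }
    structure(list(seed = as.integer(seed), nWildtypeReps = nWildtypeReps,
                   nNatural = nNatural, repsPerNatural = repsPerNatural,
                   nDeletion = nDeletion, repsPerDeletion = repsPerDeletion,
                   trialsPerCulture = trialsPerCulture,
                   naturalEffectSd = naturalEffectSd,
                   deletionEffectSd = deletionEffectSd, rho = rho,
                   cvNoiseSd = cvNoiseSd, blockWeight = blockWeight,
                   gammaShape = gammaShape, betaPrecision = betaPrecision,
                   planted = planted),
              class = "SimulationConfig")
}

## block assignment from the CalMorph-style prefix
.paramBlocks <- function(paramId) {
    b <- rep("other", length(paramId))
    b[startsWith(paramId, "C")] <- "cell"
    b[startsWith(paramId, "A")] <- "actin"
    b[startsWith(paramId, "D")] <- "nucleus"
    b[grepl("CV", paramId, fixed = TRUE)] <- "noise"
    names(b) <- paramId
    b
}

## decreasing CV--mean trend (Taylor-law-like) the Lowess stage must remove
.cvTrend <- function(m) 0.5 / sqrt(m + 0.05)

#' Simulate a replicate-level morphological trait table
#'
#' Draws culture-level values per parameter as: gamma traits from a gamma
#' with a strain-specific log-mean shift; beta traits from a mean-precision
#' beta with a logit-mean shift; overdispersed-binomial traits as
#' beta-binomial counts over \code{trialsPerCulture} cells; CV traits as a
#' deterministic decreasing function of their partner mean trait's culture
#' value plus Gaussian noise plus a strain shift. Strain effects are drawn
#' once per strain (replicates exchangeable within strain) and share a
#' per-block latent factor so the Z-score PCA has block structure. The
#' wild-type reference strain carries zero effect.
#'
#' @param config a [simConfig()] object.
#' @param catalog a \linkS4class{ParameterCatalog}.
#' @return list with \code{table} (a \linkS4class{MorphoSet}) and
#'   \code{truth}: per-strain link-scale effect matrix, the block of every
#'   parameter, planted outlier labels, and the strain group map.
#' @examples
#' cfg <- simConfig(seed = 7, nNatural = 4, nDeletion = 6)
#' cat501 <- buildDefaultCatalog()
#' sim <- simulateMorphology(cfg, cat501)
#' dim(sim$table)
#' @export
simulateMorphology <- function(config, catalog) {
    stopifnot(inherits(config, "SimulationConfig"),
              methods::is(catalog, "ParameterCatalog"))
    info <- paramInfo(catalog)
    P <- nrow(info)
    blocks <- .paramBlocks(info$param_id)

    strains <- c("BY4743",
                 sprintf("nat_%02d", seq_len(config$nNatural)),
                 sprintf("del_%03d", seq_len(config$nDeletion)))
    groups <- c("wildtype", rep("natural", config$nNatural),
                rep("deletion", config$nDeletion))
    names(groups) <- strains
    reps <- c(config$nWildtypeReps, rep(config$repsPerNatural, config$nNatural),
              rep(config$repsPerDeletion, config$nDeletion))
    for (p in config$planted)
        if (!p$strain_id %in% strains)
            stop("planted strain not in panel: ", p$strain_id)

    cultureStrain <- rep(strains, reps)
    cultureRep <- unlist(lapply(reps, seq_len))
    C <- length(cultureStrain)

    withr::with_seed(config$seed, {
        ## deterministic per-parameter baselines (link scale)
        base <- numeric(P)
        base[info$family == "gamma"] <-
            stats::runif(sum(info$family == "gamma"), log(5), log(50))
        base[info$family == "beta"] <-
            stats::runif(sum(info$family == "beta"),
                         stats::qlogis(0.1), stats::qlogis(0.5))
        base[info$family == "binomial_od"] <-
            stats::runif(sum(info$family == "binomial_od"),
                         stats::qlogis(0.1), stats::qlogis(0.5))
        base[info$family == "gaussian_cv"] <-
            stats::runif(sum(info$family == "gaussian_cv"), 0.05, 0.15)

        ## strain effects: shared block factor + idiosyncratic part
        blockNames <- unique(blocks)
        effSd <- c(wildtype = 0, natural = config$naturalEffectSd,
                   deletion = config$deletionEffectSd)[groups]
        f <- matrix(stats::rnorm(length(strains) * length(blockNames)),
                    length(strains), length(blockNames),
                    dimnames = list(strains, blockNames))
        e <- matrix(stats::rnorm(length(strains) * P), length(strains), P,
                    dimnames = list(strains, info$param_id))
        w <- config$blockWeight
        theta <- effSd * (sqrt(w) * f[, blocks[info$param_id]] +
                          sqrt(1 - w) * e)
        dimnames(theta) <- list(strains, info$param_id)
        for (p in config$planted) {
            dir <- p$direction
            shift <- ifelse(blocks[info$param_id] %in% names(dir),
                            dir[blocks[info$param_id]], 0)
            theta[p$strain_id, ] <- theta[p$strain_id, ] +
                p$magnitude * config$naturalEffectSd * shift
        }

        vals <- matrix(NA_real_, P, C,
                       dimnames = list(info$param_id,
                                       paste(cultureStrain, cultureRep,
                                             sep = "_r")))
        trials <- matrix(NA_real_, P, C, dimnames = dimnames(vals))
        thetaC <- theta[cultureStrain, , drop = FALSE]  # culture x param

        for (i in seq_len(P)) {
            fam <- info$family[i]
            eta <- base[i] + thetaC[, i]
            if (fam == "gamma") {
                k <- config$gammaShape
                vals[i, ] <- stats::rgamma(C, shape = k, rate = k / exp(eta))
            } else if (fam == "beta") {
                m <- stats::plogis(eta)
                phi <- config$betaPrecision
                y <- stats::rbeta(C, m * phi, (1 - m) * phi)
                vals[i, ] <- pmin(pmax(y, 1e-9), 1 - 1e-9)
            } else if (fam == "binomial_od") {
                pr <- stats::plogis(eta)
                n <- config$trialsPerCulture
                if (config$rho > 0) {
                    a <- pr * (1 - config$rho) / config$rho
                    b <- (1 - pr) * (1 - config$rho) / config$rho
                    pr <- stats::rbeta(C, a, b)
                }
                vals[i, ] <- stats::rbinom(C, n, pr)
                trials[i, ] <- n
            }
        }
        ## CV traits after their partners exist
        for (i in which(info$family == "gaussian_cv")) {
            j <- match(info$mean_partner_id[i], info$param_id)
            if (is.na(j))
                stop("mean partner missing for ", info$param_id[i])
            pv <- vals[j, ]
            if (info$family[j] == "binomial_od")
                pv <- pv / trials[j, ]
            vals[i, ] <- base[i] + .cvTrend(pv) + thetaC[, i] +
                stats::rnorm(C, 0, config$cvNoiseSd)
        }
    })

    cd <- data.frame(strain_id = cultureStrain, group = groups[cultureStrain],
                     replicate_index = cultureRep,
                     row.names = colnames(vals))
    table <- MorphoSet(vals, cd, catalog, trials)
    truth <- list(effects = theta, blocks = blocks,
                  planted = config$planted, groups = groups,
                  config = config)
    list(table = table, truth = truth)
}

#' Wild-type reference cultures only
#'
#' Returns the wild-type replicate cultures from the generative state of
#' [simulateMorphology()] under the same seed, suitable for null PCA and
#' Mahalanobis covariance estimation.
#'
#' @inheritParams simulateMorphology
#' @return A \linkS4class{MorphoSet} with \code{nWildtypeReps} cultures.
#' @export
nullReference <- function(config, catalog) {
    sim <- simulateMorphology(config, catalog)
    sim$table[, SummarizedExperiment::colData(sim$table)$group == "wildtype"]
}
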