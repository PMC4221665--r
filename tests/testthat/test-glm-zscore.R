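test_that("CV normalization removes the mean dependence", {
    expect_equal(eval(formals(normalizeCV)$span), 0.4)

    cat <- miniCatalog(nGamma = 2, nBeta = 0, nBinom = 0, nCv = 2)
    sim <- simulateMorphology(simConfig(seed = 2, nNatural = 5,
                                        nDeletion = 5, nWildtypeReps = 20,
                                        repsPerNatural = 3), cat)
    tab <- sim$table
    rd <- SummarizedExperiment::rowData(tab)
    vals <- SummarizedExperiment::assay(tab, "value")
    cvRows <- which(rd$family == "gaussian_cv")
    meanRow <- match(rd$mean_partner_id[cvRows], rd$param_id)

    ## constant CV: residuals ~ 0 everywhere
    vals[cvRows[1], ] <- 0.25
    ## exact smooth monotone (linear) function of the mean, no noise:
    ## the local-linear smoother reproduces it exactly
    vals[cvRows[2], ] <- 0.8 - 0.01 * vals[meanRow[2], ]
    SummarizedExperiment::assay(tab, "value") <- vals
    norm <- normalizeCV(tab)
    res <- SummarizedExperiment::assay(norm, "value")
    expect_lt(max(abs(res[cvRows[1], ])), 1e-6)
    expect_lt(max(abs(res[cvRows[2], ])), 1e-3)

    ## curved trend: residuals agree with an independent tricube
    ## local-linear oracle (both carry the same smoothing bias)
    vals[cvRows[2], ] <- 1 / (1 + vals[meanRow[2], ] / 20)
    SummarizedExperiment::assay(tab, "value") <- vals
    res2 <- SummarizedExperiment::assay(normalizeCV(tab), "value")
    x <- vals[meanRow[2], ]; y <- vals[cvRows[2], ]
    oracle <- y - localLinearOracle(x, y, span = 0.4)
    expect_lt(max(abs(res2[cvRows[2], ] - oracle)), 1e-3)

    ## missing partner column is an error naming both ids
    tab2 <- tab[setdiff(seq_len(nrow(tab)), meanRow[1]), ]
    expect_error(normalizeCV(tab2), rd$param_id[meanRow[1]])
})

test_that("strain-effect GLM matches closed forms and oracles", {
    ## gaussian identity, equal groups: z equals pooled two-sample t
    withr::with_seed(8, {
        a <- rnorm(6); b <- rnorm(6, mean = 0.7)
    })
    fit <- fitStrainEffect(a, b, "gaussian_cv")
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
    tPooled <- (mean(b) - mean(a)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    expect_equal(fit$z, tPooled, tolerance = 1e-6)
    expect_equal(fit$beta1, mean(b) - mean(a), tolerance = 1e-10)

    ## binomial with rho = 0: z equals the independent IRLS oracle
    y <- c(50, 52, 48, 100); n <- rep(200, 4); x <- c(0, 0, 0, 1)
    fit <- fitStrainEffect(y[1:3], y[4], "binomial_od",
                           refTrials = n[1:3], strainTrials = n[4])
    oracle <- irlsOracle(y, n, x)
    expect_equal(fit$z, oracle$z, tolerance = 1e-4)
    expect_equal(fit$beta1, oracle$beta[2], tolerance = 1e-6)

    ## no effect: identical constants with symmetric machine-scale jitter
    jit <- 1e-9 * c(-1, 1)
    fit <- fitStrainEffect(5 + rep(jit, 2), 5 + jit, "gaussian_cv")
    expect_lt(abs(fit$z), 0.1)
    expect_lt(abs(fit$beta1), 1e-8)

    ## gamma Wald z invariant under positive rescaling (log link)
    withr::with_seed(3, {
        g1 <- rgamma(10, 50, 5); g2 <- rgamma(4, 50, 4)
    })
    z1 <- fitStrainEffect(g1, g2, "gamma")$z
    z2 <- fitStrainEffect(10 * g1, 10 * g2, "gamma")$z
    expect_lt(abs(z1 - z2), 1e-6)

    ## support errors
    expect_error(fitStrainEffect(c(-1, 2, 3), 1, "gamma"), "positive")
    expect_error(fitStrainEffect(c(0.2, 0.3, 1), 0.5, "beta"), "open interval")
    ## zero variance flagged non-converged
    fit <- fitStrainEffect(c(2, 2, 2), 2, "gaussian_cv")
    expect_false(fit$converged)
    expect_true(is.na(fit$z))
})

test_that("Z matrix has null calibration, stability and drop behavior", {
    cat <- gammaCatalog(10)
    ## global null at many strains: entries approximately standard normal
    cfg <- simConfig(seed = 41, nNatural = 0, nDeletion = 100,
                     nWildtypeReps = 40, naturalEffectSd = 0,
                     deletionEffectSd = 0)
    sim <- simulateMorphology(cfg, cat)
    z <- zMatrix(zscoreMatrix(sim$table))
    expect_equal(dim(z), c(100L, 10L))
    ## all 100 strains share one 40-culture reference, so the per-column
    ## mean carries a common reference-sampling component (sd ~ 0.18) and
    ## the per-column sd a shared dispersion-estimate component (~ +/- 25%);
    ## bands are ~3 sigma for those statistics, tighter for pooled ones
    expect_true(all(abs(colMeans(z)) < 0.5))
    expect_true(all(apply(z, 2, sd) > 0.6 & apply(z, 2, sd) < 1.5))
    expect_lt(abs(mean(z)), 0.2)
    expect_gt(mean(apply(z, 2, sd)), 0.9)
    expect_lt(mean(apply(z, 2, sd)), 1.15)

    ## one strain only: 1 x P matrix
    cfg1 <- simConfig(seed = 42, nNatural = 0, nDeletion = 1,
                      nWildtypeReps = 10)
    z1 <- zscoreMatrix(simulateMorphology(cfg1, cat)$table)
    expect_equal(dim(zMatrix(z1)), c(1L, 10L))

    ## permuting culture rows leaves every z unchanged
    cat2 <- miniCatalog(nGamma = 3, nBeta = 1, nBinom = 1, nCv = 2)
    sim2 <- simulateMorphology(simConfig(seed = 43, nNatural = 3,
                                         nDeletion = 3, nWildtypeReps = 8,
                                         repsPerNatural = 2), cat2)
    tab <- sim2$table
    withr::with_seed(7, perm <- sample(ncol(tab)))
    zA <- zMatrix(zscoreMatrix(tab))
    zB <- zMatrix(zscoreMatrix(tab[, perm]))
    expect_equal(zA, zB[rownames(zA), colnames(zA)], tolerance = 1e-9)

    ## parameters with missing values are dropped with a count; NAs are
    ## planted in traits without CV partners so exactly 3 are lost
    rd <- SummarizedExperiment::rowData(tab)
    noPartner <- which(rd$family %in% c("beta", "binomial_od"))[1:2]
    solo <- which(rd$family == "gamma" &
                  !(rd$param_id %in% rd$mean_partner_id))[1]
    vals <- SummarizedExperiment::assay(tab, "value")
    vals[c(noPartner, solo), 2] <- NA
    SummarizedExperiment::assay(tab, "value") <- vals
    expect_message(zd <- zscoreMatrix(tab), "3 parameter")
    expect_length(droppedParams(zd), 3L)
    expect_equal(ncol(zMatrix(zd)), nrow(tab) - 3L)

    ## absent reference group is an error
    noRef <- tab[, SummarizedExperiment::colData(tab)$group != "wildtype"]
    expect_error(zscoreMatrix(noRef), "reference")
})
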