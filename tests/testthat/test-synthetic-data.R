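test_that("simulation is seed-deterministic and respects family support", {
    cat <- miniCatalog()
    cfg <- simConfig(seed = 21, nNatural = 4, nDeletion = 6,
                     nWildtypeReps = 6, repsPerNatural = 2)
    a <- simulateMorphology(cfg, cat)
    b <- simulateMorphology(cfg, cat)
    expect_identical(SummarizedExperiment::assay(a$table, "value"),
                     SummarizedExperiment::assay(b$table, "value"))
    expect_identical(a$truth$effects, b$truth$effects)

    c <- simulateMorphology(simConfig(seed = 22, nNatural = 4, nDeletion = 6,
                                      nWildtypeReps = 6,
                                      repsPerNatural = 2), cat)
    expect_false(identical(SummarizedExperiment::assay(a$table, "value"),
                           SummarizedExperiment::assay(c$table, "value")))

    ## full-table support check
    expect_true(validateTraitTable(a$table, cat)$ok)
    rd <- SummarizedExperiment::rowData(a$table)
    vals <- SummarizedExperiment::assay(a$table, "value")
    trials <- SummarizedExperiment::assay(a$table, "trials")
    expect_true(all(vals[rd$family == "gamma", ] > 0))
    expect_true(all(vals[rd$family == "beta", ] > 0 &
                    vals[rd$family == "beta", ] < 1))
    bin <- rd$family == "binomial_od"
    expect_true(all(vals[bin, ] >= 0 & vals[bin, ] <= trials[bin, ]))
    expect_true(all(trials[bin, ] >= 200))
})

test_that("null reference returns the wild-type generative state", {
    cat <- miniCatalog()
    cfg <- simConfig(seed = 9, nNatural = 3, nDeletion = 3)
    ref <- nullReference(cfg, cat)
    expect_equal(ncol(ref), 40L)
    expect_true(all(SummarizedExperiment::colData(ref)$group == "wildtype"))

    ref3 <- nullReference(simConfig(seed = 9, nWildtypeReps = 3,
                                    nNatural = 3, nDeletion = 3), cat)
    expect_equal(ncol(ref3), 3L)

    refOther <- nullReference(simConfig(seed = 10, nNatural = 3,
                                        nDeletion = 3), cat)
    expect_false(identical(SummarizedExperiment::assay(ref, "value"),
                           SummarizedExperiment::assay(refOther, "value")))
})

test_that("beta-binomial counts are overdispersed relative to binomial", {
    ## same mean, rho = 0.05 vs rho = 0: empirical variance must be larger
    cat <- ParameterCatalog(
        paramInfo(buildDefaultCatalog())[
            paramInfo(buildDefaultCatalog())$family == "binomial_od", ][1, ])
    n <- 1500
    od <- simulateMorphology(
        simConfig(seed = 4, nWildtypeReps = n, nNatural = 0, nDeletion = 0,
                  rho = 0.05), cat)
    plain <- simulateMorphology(
        simConfig(seed = 4, nWildtypeReps = n, nNatural = 0, nDeletion = 0,
                  rho = 0), cat)
    vOd <- var(as.numeric(SummarizedExperiment::assay(od$table, "value")))
    vPl <- var(as.numeric(SummarizedExperiment::assay(plain$table, "value")))
    expect_gt(vOd, vPl * 2)
    ## binomial variance at the same mean is exceeded
    m <- mean(SummarizedExperiment::assay(od$table, "value")) / 200
    expect_gt(vOd, 200 * m * (1 - m))
})

test_that("planted strains carry the promised block shift in ground truth", {
    cat <- miniCatalog()
    planted <- list(list(strain_id = "del_002",
                         direction = c(cell = 1), magnitude = 8))
    cfg <- simConfig(seed = 13, nNatural = 3, nDeletion = 4,
                     planted = planted)
    sim <- simulateMorphology(cfg, cat)
    blocks <- sim$truth$blocks
    cellParams <- names(blocks)[blocks == "cell"]
    base <- simulateMorphology(simConfig(seed = 13, nNatural = 3,
                                         nDeletion = 4), cat)
    shift <- sim$truth$effects["del_002", cellParams] -
        base$truth$effects["del_002", cellParams]
    expect_true(all(abs(shift - 8 * cfg$naturalEffectSd) < 1e-12))

    expect_error(simulateMorphology(
        simConfig(seed = 1, planted = list(list(strain_id = "nope",
                                                direction = c(cell = 1),
                                                magnitude = 2))), cat),
        "nope")
    expect_error(simConfig(planted = list(list(strain_id = "del_001",
                                               direction = c(cell = 1),
                                               magnitude = -1))),
                 "nonnegative")
})

test_that("a strongly planted strain tops the Mahalanobis ranking", {
    cat <- gammaCatalog(10)
    wins <- 0
    for (seed in 201:210) {
        cfg <- simConfig(seed = seed, nNatural = 5, nDeletion = 20,
                         nWildtypeReps = 15,
                         planted = list(list(strain_id = "del_005",
                                             direction = c(cell = 1),
                                             magnitude = 8)))
        sim <- simulateMorphology(cfg, cat)
        z <- zscoreMatrix(sim$table)
        refZ <- referenceZMatrix(sim$table)
        d <- mahalanobisDistances(z, refZ)
        del <- d[startsWith(d$strain_id, "del_"), ]
        wins <- wins + (del$strain_id[which.max(del$distance)] == "del_005")
    }
    expect_gte(wins, 9)
})

test_that("zero effect scales make strains exchangeable (null detection)", {
    ## each run has a ~5% family-wise false-positive rate by design, so
    ## detections are pooled over seeds and bounded
    cat <- gammaCatalog(8)
    totalDetections <- 0
    for (seed in 31:33) {
        cfg <- simConfig(seed = seed, nNatural = 10, nDeletion = 15,
                         nWildtypeReps = 10, naturalEffectSd = 0,
                         deletionEffectSd = 0)
        sim <- simulateMorphology(cfg, cat)
        z <- suppressMessages(zscoreMatrix(sim$table))
        pcm <- pcaZ(z)
        sc <- pcScores(pcm)
        ctr <- projectScores(pcm, matrix(0, 1, ncol(zMatrix(z)),
                                         dimnames = list("BY4743",
                                                         colnames(zMatrix(z)))))
        grp <- sim$truth$groups[rownames(sc)]
        det <- detectHeteroclites(sc[grp == "deletion", 1:4, drop = FALSE],
                                  sc[grp == "natural", 1:4, drop = FALSE],
                                  center = as.numeric(ctr)[1:4],
                                  components = 1:4)
        totalDetections <- totalDetections + length(det$heteroclites)
    }
    expect_lte(totalDetections, 2L)
})
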