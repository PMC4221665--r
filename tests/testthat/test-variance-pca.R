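test_that("variance estimators use the assay's df conventions", {
    ## two parental triplicates, each centered by its own mean: df 4
    by <- c(0.1, 0.3, 0.2); rm <- c(1.1, 0.9, 1.3)
    v <- perTraitVariance(c(by, rm), "per_subgroup_mean",
                          groups = rep(c("BY", "RM"), each = 3))
    expect_equal(v$df_used, 4L)
    ssq <- sum((by - mean(by))^2) + sum((rm - mean(rm))^2)
    expect_equal(v$variance, ssq / 4)

    ## 37 strains about their common mean: df 36
    withr::with_seed(4, x <- rnorm(37))
    v37 <- perTraitVariance(x, "own_mean")
    expect_equal(v37$df_used, 36L)
    expect_equal(v37$variance, var(x))

    ## 110 strains: df 109
    withr::with_seed(5, y <- rnorm(110))
    expect_equal(perTraitVariance(y, "own_mean")$df_used, 109L)

    ## external reference center: divisor n
    vr <- perTraitVariance(c(-1, 1), "reference_mean", center = 0)
    expect_equal(vr$variance, 1)
    expect_equal(vr$df_used, 2L)

    expect_equal(perTraitVariance(c(2, 2, 2), "own_mean")$variance, 0)
    expect_error(perTraitVariance(1, "own_mean"), ">= 2")
})

test_that("variance-ratio profile counts strict exceedances", {
    withr::with_seed(6, a <- matrix(rnorm(50 * 7), 50, 7,
                                    dimnames = list(NULL, paste0("p", 1:7))))
    same <- varianceRatioProfile(a, a)
    expect_equal(unname(same$ratio), rep(1, 7))
    expect_equal(same$exceed_count, 0L)  # strict >

    one <- varianceRatioProfile(a[, 1, drop = FALSE], a[, 1, drop = FALSE])
    expect_length(one$ratio, 1L)

    ## zero denominator flagged infinite and excluded
    b <- a; b[, 2] <- 5
    r <- suppressMessages(varianceRatioProfile(a, b))
    expect_true(is.infinite(r$ratio["p2"]))
    expect_equal(r$excluded, "p2")
})

test_that("inflated deletion effects push most variance ratios above 1", {
    cat <- gammaCatalog(20)
    cfg <- simConfig(seed = 51, nNatural = 30, nDeletion = 60,
                     nWildtypeReps = 40, repsPerNatural = 5,
                     repsPerDeletion = 1)
    sim <- simulateMorphology(cfg, cat)
    z <- zMatrix(zscoreMatrix(sim$table))
    grp <- sim$truth$groups[rownames(z)]
    r <- varianceRatioProfile(z[grp == "deletion", ], z[grp == "natural", ])
    expect_gte(r$exceed_count / r$n_shared, 0.9)
})

test_that("under symmetric null conditions the exceedance rate is ~ 1/2", {
    cat <- gammaCatalog(20)
    hits <- 0; total <- 0
    for (seed in 61:65) {
        cfg <- simConfig(seed = seed, nNatural = 25, nDeletion = 25,
                         nWildtypeReps = 20, repsPerNatural = 2,
                         repsPerDeletion = 2, naturalEffectSd = 0.3,
                         deletionEffectSd = 0.3)
        sim <- simulateMorphology(cfg, cat)
        z <- zMatrix(zscoreMatrix(sim$table))
        grp <- sim$truth$groups[rownames(z)]
        r <- varianceRatioProfile(z[grp == "deletion", ],
                                  z[grp == "natural", ])
        hits <- hits + r$exceed_count; total <- total + r$n_shared
    }
    expect_gt(hits / total, 0.4)
    expect_lt(hits / total, 0.6)
})

test_that("PCA agrees with an independent eigendecomposition oracle", {
    withr::with_seed(12, m <- matrix(rnorm(20), 5, 4,
                                     dimnames = list(paste0("s", 1:5),
                                                     paste0("p", 1:4))))
    pcm <- pcaZ(m)
    eo <- eigen(cov(m), symmetric = TRUE)
    k <- ncol(pcScores(pcm))
    expect_equal(varExplained(pcm), eo$values[seq_len(k)], tolerance = 1e-8)
    for (j in seq_len(k))
        expect_equal(abs(pcLoadings(pcm)[, j]), abs(eo$vectors[, j]),
                     tolerance = 1e-8, ignore_attr = TRUE)

    ## scores orthogonal; cumulative ratio ends at 1; variance conserved
    sc <- pcScores(pcm)
    cc <- cor(sc)
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
    expect_equal(sum(cumsum(propVarExplained(pcm))[k]), 1, tolerance = 1e-12)
    expect_equal(sum(varExplained(pcm)), sum(apply(m, 2, var)),
                 tolerance = 1e-8)

    ## exact rank 2: no variance beyond component 2
    withr::with_seed(13, {
        u <- matrix(rnorm(12), 6, 2); v <- matrix(rnorm(10), 2, 5)
    })
    low <- u %*% v
    dimnames(low) <- list(paste0("s", 1:6), paste0("p", 1:5))
    pl <- pcaZ(low)
    expect_lt(sum(varExplained(pl)[-(1:2)]), 1e-10)

    expect_error(pcaZ(matrix(1, 4, 3)), "constant")
})

test_that("equiprobability ellipse matches the chi-square closed form", {
    ## large sample from an isotropic normal: 95% contour radius^2 ~ 5.991
    pts <- refWithCovariance(4000, diag(2), seed = 21)
    ell <- equiprobabilityEllipse(pts, massLevel = 0.95)
    expect_equal(dim(ell$grid$density), c(200L, 200L))

    ## radius of the contour from the density level: for N(mu, I),
    ## level = exp(-r^2/2) / (2 pi)
    r2 <- -2 * log(ell$level * 2 * pi * sqrt(det(ell$cov)))
    expect_equal(r2, qchisq(0.95, df = 2), tolerance = 0.02)

    ## enclosed area matches pi * r^2 * sqrt(det Sigma) within 2%
    analytic <- pi * qchisq(0.95, 2) * sqrt(det(ell$cov))
    expect_equal(ell$area, analytic, tolerance = 0.02)

    ## grid mass is a proper (sub-)probability
    cell <- diff(ell$grid$x[1:2]) * diff(ell$grid$y[1:2])
    expect_lte(sum(ell$grid$density) * cell, 1 + 1e-6)

    ## collinear points are an error
    line <- cbind(1:5, 2 * (1:5))
    expect_error(equiprobabilityEllipse(line), "collinear|singular")
})

test_that("broadness ratio follows the determinant-root closed form", {
    a <- refWithCovariance(500, diag(2), seed = 31)
    ellA <- equiprobabilityEllipse(a)
    expect_equal(as.numeric(broadnessRatio(ellA, ellA)), 1)

    b <- a * 2  # covariance scales by 4 => area by sqrt(det) = 4
    ellB <- equiprobabilityEllipse(b)
    expect_equal(as.numeric(broadnessRatio(ellB, ellA)), 4, tolerance = 1e-9)

    ## reciprocal property
    expect_equal(as.numeric(broadnessRatio(ellA, ellB)) *
                 as.numeric(broadnessRatio(ellB, ellA)), 1,
                 tolerance = 1e-9)

    ## mixture of two point sets uses the pooled moments
    c2 <- sweep(a, 2, c(5, 0), "+")
    ellMix <- equiprobabilityEllipse(a, mixture = c2)
    expect_gt(det(ellMix$cov), det(ellA$cov))
})

test_that("deletion scores are broader than natural scores by simulation", {
    cat <- gammaCatalog(15)
    wins <- 0
    for (seed in 71:78) {
        cfg <- simConfig(seed = seed, nNatural = 15, nDeletion = 25,
                         nWildtypeReps = 15)
        sim <- simulateMorphology(cfg, cat)
        z <- zMatrix(zscoreMatrix(sim$table))
        grp <- sim$truth$groups[rownames(z)]
        pcm <- pcaZ(z)
        sc <- pcScores(pcm)[, 1:2]
        eD <- equiprobabilityEllipse(sc[grp == "deletion", ], gridSize = 50)
        eN <- equiprobabilityEllipse(sc[grp == "natural", ], gridSize = 50)
        wins <- wins + (as.numeric(broadnessRatio(eD, eN)) > 1)
    }
    expect_gte(wins, 7)
})
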