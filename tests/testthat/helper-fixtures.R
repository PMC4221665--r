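## Shared fixtures and independent oracles for the test suite.

## small catalog drawn from the default one: a few parameters per family
miniCatalog <- function(nGamma = 6, nBeta = 3, nBinom = 3, nCv = 6) {
    info <- paramInfo(buildDefaultCatalog())
    keep <- rbind(
        info[info$family == "gamma", ][seq_len(nGamma), ],
        info[info$family == "beta", ][seq_len(nBeta), ],
        info[info$family == "binomial_od", ][seq_len(nBinom), ],
        info[info$family == "gaussian_cv", ][seq_len(nCv), ])
    ## CV partners are the first gamma parameters by construction
    keep <- keep[!(keep$family == "gaussian_cv" &
                   !(keep$mean_partner_id %in% keep$param_id)), ]
    ParameterCatalog(keep)
}

## gamma-only catalog: fastest fits, used for simulation-heavy properties
gammaCatalog <- function(n = 20) {
    info <- paramInfo(buildDefaultCatalog())
    ParameterCatalog(info[info$family == "gamma", ][seq_len(n), ])
}

## ---- independent oracles ---------------------------------------------------

## IRLS for the two-group logistic model with Pearson-based dispersion,
## written from the normal equations (no glm machinery)
irlsOracle <- function(y, n, x) {
    X <- cbind(1, x)
    beta <- c(stats::qlogis((sum(y) + 0.5) / (sum(n) + 1)), 0)
    for (it in 1:200) {
        eta <- as.numeric(X %*% beta)
        mu <- 1 / (1 + exp(-eta))
        W <- n * mu * (1 - mu)
        zw <- eta + (y - n * mu) / W
        betaNew <- solve(t(X) %*% (W * X), t(X) %*% (W * zw))
        if (max(abs(betaNew - beta)) < 1e-13) { beta <- betaNew; break }
        beta <- betaNew
    }
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    pearson <- sum((y - n * mu)^2 / (n * mu * (1 - mu)))
    phi <- pearson / (length(y) - 2)
    covb <- phi * solve(t(X) %*% ((n * mu * (1 - mu)) * X))
    list(beta = as.numeric(beta), se = sqrt(diag(covb)),
         z = beta[2] / sqrt(covb[2, 2]))
}

## standard normal CDF by numeric integration of the density formula
phiOracle <- function(x) {
    dens <- function(t) exp(-t^2 / 2) / sqrt(2 * pi)
    0.5 + sign(x) * stats::integrate(dens, 0, abs(x),
                                     rel.tol = 1e-12)$value
}

## complete-linkage agglomeration by explicit enumeration of cluster pairs
completeLinkageOracle <- function(D) {
    D <- as.matrix(D)
    clusters <- as.list(seq_len(nrow(D)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- c(NA, NA); bh <- Inf
        for (i in seq_len(length(clusters) - 1))
            for (j in (i + 1):length(clusters)) {
                h <- max(D[clusters[[i]], clusters[[j]]])
                if (h < bh) { bh <- h; best <- c(i, j) }
            }
        heights <- c(heights, bh)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    sort(heights)
}

## exact two-sided Mann-Whitney p by enumeration of all group labelings
mannWhitneyEnumOracle <- function(a, b) {
    pool <- c(a, b)
    na <- length(a)
    uStat <- function(idx) {
        ga <- pool[idx]; gb <- pool[-idx]
        sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
    }
    uObs <- uStat(seq_len(na))
    us <- apply(utils::combn(length(pool), na), 2, uStat)
    mu <- na * (length(pool) - na) / 2
    mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

## local-linear tricube regression with bisquare robustness iterations
## (the lowess smoother, written from its definition)
localLinearOracle <- function(x, y, span, iter = 3, xout = x) {
    fitAt <- function(w0, xout) {
        n <- length(x)
        q <- max(2, ceiling(span * n))
        vapply(xout, function(x0) {
            d <- abs(x - x0)
            h <- sort(d)[q]
            w <- pmax(0, (1 - pmin(d / max(h, 1e-12), 1)^3))^3 * w0
            X <- cbind(1, x - x0)
            b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
            b[1]
        }, numeric(1))
    }
    fit <- fitAt(rep(1, length(x)), x)
    for (it in seq_len(iter)) {
        res <- y - fit
        s <- stats::median(abs(res))
        wr <- if (s > 0) (pmax(0, 1 - (res / (6 * s))^2))^2
              else rep(1, length(x))
        fit <- fitAt(wr, x)
    }
    if (identical(xout, x)) fit else fitAt(wr, xout)
}

## reference replicate matrix with an exact prescribed sample covariance
refWithCovariance <- function(n, sigma, seed = 1) {
    withr::with_seed(seed, {
        M <- matrix(stats::rnorm(n * nrow(sigma)), n, nrow(sigma))
        M <- scale(M, scale = FALSE)
        M <- M %*% solve(chol(stats::cov(M)))
        M %*% chol(sigma)
    })
}
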