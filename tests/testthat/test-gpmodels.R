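# GRM, GBLUP/REML, BayesB, multi-trait models and prediction.

test_that("GRM reproduces a hand-computed toy example", {
    # 4 individuals x 3 markers, worked through the VanRaden formula
    W <- rbind(c(0, 1, 2), c(2, 1, 0), c(1, 1, 1), c(2, 2, 2))
    p <- colMeans(W) / 2
    C <- sweep(W, 2, 2 * p)
    want <- C %*% t(C) / (2 * sum(p * (1 - p)))
    g <- computeGRM(W)
    expect_lt(max(abs(relMatrix(g) - want)), 1e-8)
    expect_equal(g@normConstant, 2 * sum(p * (1 - p)))
})

test_that("GRM handles identical individuals and monomorphic markers", {
    W <- rbind(a = c(0, 2, 1, 0), b = c(0, 2, 1, 0), c = c(2, 0, 1, 2))
    colnames(W) <- paste0("M", 1:4)
    g <- suppressMessages(computeGRM(cbind(W, M5 = c(0, 0, 0))))
    G <- relMatrix(g)
    # two identical individuals: off-diagonal equals each diagonal
    expect_equal(G[1, 2], G[1, 1], tolerance = 1e-12)
    expect_identical(g@excluded, "M5")
    expect_error(computeGRM(cbind(c(NA, 0, 1))), "missing")
})

test_that("GRM mean diagonal is near 1 at Hardy-Weinberg-like frequencies", {
    W <- hwePanel(400, 600, seed = 3)
    g <- computeGRM(W)
    md <- mean(diag(relMatrix(g)))
    expect_gt(md, 0.9); expect_lt(md, 1.1)
})

test_that("GBLUP equals the ridge-regression oracle at matched lambda", {
    set.seed(8)
    n <- 50; m <- 100
    W <- hwePanel(n, m, seed = 8)
    y <- rnorm(n) + W %*% rnorm(m, 0, 0.05)
    g <- computeGRM(W)
    fit <- fitGBLUP(drop(y), g)
    lambda <- fit@sigma2u / fit@sigma2e
    p <- colMeans(W) / 2
    Csc <- sweep(W, 2, 2 * p)
    # GBLUP u = lambda*G(lambda*G+I)^-1 r  ==  ridge with penalty c/lambda
    r <- drop(y) - drop(fit@beta)
    uRidge <- oracleRidgePredict(r, Csc, g@normConstant / lambda)
    expect_lt(max(abs(geneticValues(fit) - uRidge)), 1e-8)
})

test_that("GBLUP degenerate inputs", {
    g <- computeGRM(hwePanel(30, 50, seed = 4))
    expect_error(fitGBLUP(rep(1, 30), g), "variance")
    expect_error(fitGBLUP(rnorm(10), relMatrix(g)[1:10, 1:10],
                          X = cbind(1, 1:10, 2 * (1:10))), "rank")
})

test_that("REML recovers simulated heritability and nulls stay near zero", {
    h2hat <- function(h2, seed) {
        sim <- smallCrossSim(nChrom = 3, markersPerChrom = 15,
            f2Lines = 80, f2Selected = 60, seedsPerLine = 2, f3Sel = 30,
            arch = list(traitArchitecture(nPolygenes = 45, polygeneSD = 0.1,
                                          targetH2 = h2)),
            seed = seed)
        mm <- sim$genotypes$F3
        y <- sim$phenotypes$trait1[sim$phenotypes$generation == "F3"]
        heritability(fitGBLUP(y, computeGRM(mm)))
    }
    # small-scale variant (n ~ 120, m = 45) of the recovery check; the
    # spec-scale version (n = 300, m = 1000) runs in the acceptance suite
    est <- vapply(1:8, function(s) h2hat(0.7, 300 + s), numeric(1))
    expect_lt(abs(mean(est) - 0.7), 0.15)
    nulls <- vapply(1:8, function(s) h2hat(0, 400 + s), numeric(1))
    expect_lt(median(nulls), 0.1)
})

test_that("population-mean fixed effects are recovered; permutation invariance", {
    set.seed(9)
    n <- 150
    W <- hwePanel(n, 200, seed = 9)
    G <- relMatrix(computeGRM(W))
    pop <- rep(c("a", "b", "c"), each = n / 3)
    mu <- c(a = 0, b = 5, c = -5)
    y <- mu[pop] + rnorm(n)
    fit <- fitGBLUPMultipop(y, pop, G)
    expect_equal(unname(fixedEffects(fit)[c("a", "b", "c")]),
                 unname(mu), tolerance = 0.5)
    expect_lt(heritability(fit), 0.25)
    # permuting individual order permutes nothing about the estimates
    ord <- sample(n)
    fit2 <- fitGBLUPMultipop(y[ord], pop[ord], G[ord, ord])
    expect_equal(varComponents(fit2), varComponents(fit), tolerance = 1e-5)
    expect_equal(fixedEffects(fit2), fixedEffects(fit), tolerance = 1e-5)
    # single population reduces to the intercept-only model
    one <- fitGBLUPMultipop(y[1:50], rep("a", 50), G[1:50, 1:50])
    ref <- fitGBLUP(y[1:50], G[1:50, 1:50])
    expect_equal(varComponents(one), varComponents(ref), tolerance = 1e-8)
    expect_error(fitGBLUPMultipop(y, c("solo", pop[-1]), G), "at least 2")
})

test_that("GBLUP predicts held-out individuals through the joint GRM", {
    sim <- smallCrossSim(nChrom = 3, markersPerChrom = 15,
        f2Lines = 80, f2Selected = 60, seedsPerLine = 2, f3Sel = 30,
        arch = list(traitArchitecture(nPolygenes = 45, polygeneSD = 0.1,
                                      targetH2 = 0.8)),
        seed = 88)
    mm <- sim$genotypes$F3
    y <- sim$phenotypes$trait1[sim$phenotypes$generation == "F3"]
    G <- computeGRM(mm)
    hold <- seq(1, length(y), by = 4)
    yNA <- y; yNA[hold] <- NA
    fit <- fitGBLUP(yNA, G)
    expect_gt(cor(predict(fit)[hold], y[hold]), 0.4)
    # self-prediction equals the in-sample fitted values
    fitAll <- fitGBLUP(y, G)
    expect_equal(cor(predict(fitAll), y),
                 cor(fitAll@fitted, y), tolerance = 1e-12)
})

test_that("BayesB shrinks nulls, finds a large QTL, and is seed-stable", {
    set.seed(10)
    n <- 150; m <- 200
    W <- hwePanel(n, m, seed = 10)
    # null trait: strong shrinkage, low inclusion
    y0 <- rnorm(n)
    f0 <- fitBayesB(y0, W, nIter = 1200, burnIn = 300, seed = 1)
    expect_lt(mean(abs(markerEffects(f0))), 0.1 * sd(y0))
    expect_lt(mean(inclusionProb(f0)), 0.5)
    # one marker explaining half the variance
    g <- W[, 77] - 1
    y1 <- g + rnorm(n, 0, sd(g))
    f1 <- fitBayesB(y1, W, nIter = 1500, burnIn = 400, seed = 2)
    expect_identical(unname(which.max(abs(markerEffects(f1)))), 77L)
    expect_gt(inclusionProb(f1)[77], 0.9)
    # bit-identical reruns under the same seed
    f1b <- fitBayesB(y1, W, nIter = 1500, burnIn = 400, seed = 2)
    expect_identical(markerEffects(f1), markerEffects(f1b))
    expect_identical(f1@pi, f1b@pi)
    expect_error(fitBayesB(y1, W, nIter = 100, burnIn = 200), "nIter")
})

test_that("marker-effect prediction checks marker compatibility", {
    W <- hwePanel(60, 50, seed = 12)
    y <- rnorm(60)
    fit <- fitBayesB(y, W, nIter = 600, burnIn = 100, seed = 3)
    pred <- predictMarkers(fit, W)
    expect_length(pred, 60)
    # permuting test individuals permutes predictions identically
    ord <- sample(60)
    expect_equal(predictMarkers(fit, W[ord, ]), pred[ord])
    expect_error(predictMarkers(fit, W[, 1:40]), "mismatch")
})

test_that("noise-free oligogenic trait is predicted almost perfectly", {
    sim <- smallCrossSim(nChrom = 2, markersPerChrom = 10,
        f2Lines = 100, f2Selected = 80, seedsPerLine = 2, f3Sel = 40,
        arch = list(traitArchitecture(
            qtl = data.frame(chrom = c(1, 2), posCM = c(20, 40),
                             effect = c(1, 0.5)),
            targetH2 = 1)),
        seed = 93)
    mm <- sim$genotypes$F3
    y <- sim$phenotypes$trait1[sim$phenotypes$generation == "F3"]
    W <- genoScores(mm)
    train <- seq_len(floor(0.7 * length(y)))
    test <- setdiff(seq_along(y), train)
    fit <- fitBayesB(y[train], W[train, ], nIter = 2000, burnIn = 500,
                     seed = 4)
    expect_gt(cor(predictMarkers(fit, W[test, ]), y[test]), 0.95)
})

test_that("multi-trait GBLUP recovers genetic covariance structure", {
    set.seed(14)
    n <- 250; m <- 400; ne <- 150
    W <- hwePanel(n, m, seed = 14)
    G <- computeGRM(W)
    Sigma <- matrix(c(1, 0.6, 0.6, 1), 2) / ne
    Bm <- matrix(rnorm(ne * 2), ne, 2) %*% chol(Sigma)
    Gv <- W[, seq_len(ne)] %*% Bm
    Y <- Gv + cbind(rnorm(n, 0, sd(Gv[, 1]) * sqrt(2 / 3)),
                    rnorm(n, 0, sd(Gv[, 2]) * sqrt(2 / 3)))
    mt <- fitMultitraitGBLUP(Y, G)
    expect_equal(geneticCorrelations(mt)[1, 2], 0.6, tolerance = 0.15)
    # per-trait h2 agrees with the single-trait fits
    h1 <- heritability(fitGBLUP(Y[, 1], G))
    h2 <- heritability(fitGBLUP(Y[, 2], G))
    expect_lt(max(abs(heritability(mt) - c(h1, h2))), 0.05)
})

test_that("independent traits give near-zero genetic correlation", {
    set.seed(15)
    n <- 200; m <- 300; ne <- 100
    W <- hwePanel(n, m, seed = 15)
    G <- computeGRM(W)
    g1 <- W[, 1:ne] %*% rnorm(ne, 0, sqrt(1 / ne))
    g2 <- W[, (ne + 1):(2 * ne)] %*% rnorm(ne, 0, sqrt(1 / ne))
    Y <- cbind(g1 + rnorm(n, 0, sd(g1)), g2 + rnorm(n, 0, sd(g2)))
    mt <- fitMultitraitGBLUP(Y, G)
    expect_lt(abs(geneticCorrelations(mt)[1, 2]), 0.3)
})

test_that("duplicated trait columns are flagged as degenerate, not fatal", {
    set.seed(16)
    W <- hwePanel(100, 150, seed = 16)
    G <- computeGRM(W)
    y <- drop(W[, 1:50] %*% rnorm(50, 0, 0.1)) + rnorm(100, 0, 0.5)
    mt <- suppressWarnings(fitMultitraitGBLUP(cbind(y, y), G))
    expect_equal(geneticCorrelations(mt)[1, 2], 1, tolerance = 0.02)
})

test_that("multi-trait BayesC-pi reduces to single-trait and shrinks selectively", {
    set.seed(17)
    n <- 150; m <- 150
    W <- hwePanel(n, m, seed = 17)
    g <- W[, 40] - 1
    y <- drop(g + rnorm(n, 0, sd(g)))
    # t = 1 reduction: predictions track BayesB closely
    cp1 <- fitMultitraitBayesCpi(cbind(y), W, nIter = 1500, burnIn = 400,
                                 seed = 5)
    bb <- fitBayesB(y, W, nIter = 1500, burnIn = 400, seed = 5)
    expect_gt(cor(predictMarkers(cp1, W), predictMarkers(bb, W)), 0.95)
    # marker affecting trait 1 only, independent trait 2
    y2 <- rnorm(n)
    cp2 <- fitMultitraitBayesCpi(cbind(t1 = y, t2 = y2), W,
                                 nIter = 1500, burnIn = 400, seed = 6)
    expect_gt(inclusionProb(cp2)[40], 0.8)
    eff <- markerEffects(cp2)
    expect_gt(abs(eff[40, "t1"]), 3 * abs(eff[40, "t2"]))
    # seeded determinism
    cp2b <- fitMultitraitBayesCpi(cbind(t1 = y, t2 = y2), W,
                                  nIter = 1500, burnIn = 400, seed = 6)
    expect_identical(markerEffects(cp2), markerEffects(cp2b))
})
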