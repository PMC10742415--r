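## Genomic prediction: GRM, single-trait GBLUP (EMMA-style REML),
## BayesB, multi-trait GBLUP (EM-REML in the GRM eigenbasis) and
## multi-trait BayesC-pi.  The mixed model is
##   y = X beta + Z u + e,  u ~ MVN(0, G sigma2u),  e ~ MVN(0, I sigma2e)
## with one phenotype record per genotype (Z = I), and genomic
## heritability h2 = sigma2u / (sigma2u + sigma2e).

#' Genomic relationship matrix (VanRaden linear kernel)
#'
#' Each marker column is centered by twice its allele frequency and the
#' cross-product is divided by a normalization constant:
#' G = C C' / c.  With `normalization = "binomial"` (default) the
#' constant is the textbook VanRaden c = 2 * sum(p (1 - p)), under
#' which the mean diagonal is near 1 at Hardy-Weinberg-like genotype
#' frequencies.  In selfing-derived F_t populations the heterozygote
#' deficit inflates marker variances by (1 + F), so the binomial
#' constant leaves a mean diagonal of about 1 + F (~1.5 at F3) and the
#' variance ratio sigma2u/(sigma2u + sigma2e) then understates the
#' realized heritability; `normalization = "observed"` divides by the
#' summed observed marker variances instead, which makes the mean
#' diagonal exactly 1 in any population and keeps sigma2u on the
#' phenotypic scale — the appropriate choice for F_t panels, and the
#' one the pipeline uses.  Allele frequencies and variances are
#' computed over all individuals supplied (pooled across populations);
#' pass per-population subsets for per-population frequencies.
#' Monomorphic markers carry no information and are excluded from the
#' kernel (logged in the result).  If the smallest eigenvalue is below
#' zero a documented ridge of 1e-6 is added to the diagonal.
#'
#' @param mm a [MarkerMatrix-class] or a numeric score matrix
#'   (individuals x markers), complete (impute first)
#' @param normalization "binomial" (2 sum p(1-p)) or "observed"
#'   (summed observed marker variances; mean diagonal exactly 1)
#' @return a [GRM-class]
#' @export
computeGRM <- function(mm, normalization = c("binomial", "observed")) {
    normalization <- match.arg(normalization)
    sc <- if (is(mm, "MarkerMatrix")) genoScores(mm) else as.matrix(mm)
    if (anyNA(sc)) stop("scores contain missing values; run imputeMissing() first")
    p <- colMeans(sc) / 2
    mono <- p <= 0 | p >= 1
    excluded <- colnames(sc)[mono] %||% character()
    if (any(mono)) {
        message("computeGRM: excluding ", sum(mono), " monomorphic marker(s)")
        sc <- sc[, !mono, drop = FALSE]
        p <- p[!mono]
    }
    if (!ncol(sc)) stop("no polymorphic markers left")
    C <- sweep(sc, 2, 2 * p)
    denom <- if (normalization == "binomial") 2 * sum(p * (1 - p))
             else sum(colMeans(C^2))
    G <- tcrossprod(C) / denom
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
        G <- G + diag(1e-6, nrow(G))
        warning("GRM not PSD; added ridge 1e-6 to the diagonal")
    }
    new("GRM", G = G, normConstant = denom,
        excluded = as.character(excluded))
}

## REML profile over lambda = sigma2u / sigma2e on the eigenbasis of G.
## Returns the restricted log-likelihood (up to a constant) at lambda.
.remlProfile <- function(lambda, S, Ys, Xs) {
    n <- length(Ys); p <- ncol(Xs)
    d <- lambda * S + 1
    Xd <- Xs / d
    XtVX <- crossprod(Xs, Xd)
    beta <- solve(XtVX, crossprod(Xd, Ys))
    r <- Ys - Xs %*% beta
    rss <- sum(r^2 / d)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2e) + sum(log(d)) +
                  determinant(XtVX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), beta = drop(beta), s2e = s2e)
}

#' Single-trait GBLUP with REML variance components
#'
#' Variance components are estimated by REML profiled over
#' lambda = sigma2u/sigma2e on a single eigendecomposition of G
#' (EMMA-style): a coarse log-scale grid over lambda is refined by
#' bounded scalar optimization.  Individuals with missing phenotype are
#' excluded from estimation and receive genomic predictions through the
#' relationship matrix: u = sigma2u * G[, obs] V^{-1} (y - X beta),
#' the standard joint-GRM prediction.  Boundary estimates of sigma2u are
#' clamped at 1e-8 times the phenotypic variance.
#'
#' @param y phenotype vector; NA entries are predicted, not fitted
#' @param G a [GRM-class] or relationship matrix over all individuals of
#'   `y`
#' @param X fixed-effect design matrix over all individuals (default:
#'   intercept only); must be full column rank on the observed subset
#' @return a [GPFit-class]
#' @export
fitGBLUP <- function(y, G, X = NULL) {
    if (is(G, "GRM")) G <- relMatrix(G)
    n <- length(y)
    stopifnot(nrow(G) == n)
    if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    X <- as.matrix(X)
    obs <- which(!is.na(y))
    if (length(obs) < ncol(X) + 2) stop("too few phenotyped individuals")
    yo <- y[obs]
    if (var(yo) == 0) stop("phenotype has zero variance")
    Xo <- X[obs, , drop = FALSE]
    if (qr(Xo)$rank < ncol(Xo)) stop("X is rank deficient on the observed subset")
    eg <- eigen(G[obs, obs], symmetric = TRUE)
    S <- pmax(eg$values, 0)
    U <- eg$vectors
    Ys <- drop(crossprod(U, yo))
    Xs <- crossprod(U, Xo)

    grid <- 10^seq(-5, 5, length.out = 41)
    lls <- vapply(grid, function(l) .remlProfile(l, S, Ys, Xs)$ll, numeric(1))
    best <- which.max(lls)
    lo <- log(grid[max(1, best - 1)]); hi <- log(grid[min(length(grid), best + 1)])
    opt <- optimize(function(ll) .remlProfile(exp(ll), S, Ys, Xs)$ll,
                    c(lo, hi), maximum = TRUE, tol = 1e-8)
    lambda <- exp(opt$maximum)
    if (opt$objective < lls[best]) lambda <- grid[best]
    fit <- .remlProfile(lambda, S, Ys, Xs)
    s2e <- fit$s2e
    s2u <- lambda * s2e
    floor_ <- 1e-8 * var(yo)
    if (s2u < floor_) { s2u <- floor_ }
    h2 <- s2u / (s2u + s2e)
    # BLUP for all individuals through the joint relationship matrix
    d <- lambda * S + 1
    resid <- yo - Xo %*% fit$beta
    w <- U %*% ((crossprod(U, resid)) / d)     # Vinv * resid * s2e
    u <- drop(lambda * G[, obs] %*% w)
    beta <- fit$beta
    names(beta) <- colnames(X)
    fitted <- drop(X %*% beta) + u
    names(u) <- names(fitted) <- rownames(G) %||% as.character(seq_len(n))
    new("GPFit", beta = beta, u = u, sigma2u = s2u, sigma2e = s2e,
        h2 = h2, logLik = fit$ll, fitted = fitted, model = "GBLUP")
}

#' GBLUP with population-mean fixed effects
#'
#' As [fitGBLUP] with the fixed-effect design replaced by a
#' population-indicator matrix (one column per population, no global
#' intercept), so the betas are the population means — the multi-cross
#' model in which Xb corrects for the average effect of each population.
#' A single population reduces to the intercept-only fit.
#'
#' @param y phenotype vector (NA = predict)
#' @param population population label per individual
#' @param G relationship matrix or [GRM-class] over all individuals
#' @return a [GPFit-class]; betas named by population
#' @export
fitGBLUPMultipop <- function(y, population, G) {
    population <- as.factor(population)
    if (any(table(population) < 2))
        stop("every population needs at least 2 individuals")
    lev <- levels(population)
    X <- vapply(lev, function(l) as.numeric(population == l),
                numeric(length(population)))
    colnames(X) <- lev
    fitGBLUP(y, G, X = X)
}

#' Predicted values of a fitted GBLUP model
#'
#' @param object a [GPFit-class]
#' @param ... unused
#' @return fitted values X beta + u for every individual in the
#'   relationship matrix, including unphenotyped ones
#' @export
setMethod("predict", "GPFit", function(object, ...) object@fitted)

#' BayesB whole-genome regression
#'
#' Gibbs sampler for y = X beta + W a + e with the BayesB mixture prior
#' on each marker effect: a point mass at zero with probability pi (the
#' exclusion mass, given a Beta prior and updated) and a slab that is a
#' scaled-t distribution, implemented as a normal with its own marker
#' variance under a scaled-inverse-chi-square prior (df `df`, scale set
#' from a phenotypic-variance heuristic unless supplied).  Fully seeded
#' and reproducible.
#'
#' @param y complete phenotype vector
#' @param W marker score matrix (individuals x markers)
#' @param X fixed-effect design (default intercept)
#' @param nIter,burnIn chain length and burn-in
#' @param df slab degrees of freedom
#' @param scale slab scale; NULL for the heuristic (half the phenotypic
#'   variance spread over the expected included markers)
#' @param piPrior Beta(a, b) prior on the exclusion mass pi (default
#'   Beta(9, 1): sparse start, about 10% of markers in the model)
#' @param seed RNG seed
#' @return a [MarkerEffectFit-class]
#' @export
fitBayesB <- function(y, W, X = NULL, nIter = 12000, burnIn = 2000,
                      df = 5, scale = NULL, piPrior = c(9, 1), seed = 1) {
    stopifnot(nIter > burnIn, burnIn >= 0)
    if (anyNA(y)) stop("phenotype must be complete (subset before fitting)")
    W <- as.matrix(W)
    n <- length(y)
    stopifnot(nrow(W) == n)
    if (is.null(X)) X <- matrix(1, n, 1)
    X <- as.matrix(X)
    if (is.null(scale)) {
        piBar <- piPrior[1] / sum(piPrior)
        sumVar <- sum(apply(W, 2, var))
        scale <- 0.5 * var(y) * (df - 2) / (df * max(1e-8, (1 - piBar) * sumVar))
    }
    set.seed(seed)
    res <- bayesb_gibbs(y, X, W, as.integer(nIter), as.integer(burnIn),
                        df, scale, piPrior[1], piPrior[2])
    if (!all(is.finite(res$effects)))
        stop("divergent chain: non-finite samples")
    effects <- matrix(res$effects, ncol = 1,
                      dimnames = list(colnames(W), "trait1"))
    new("MarkerEffectFit", effects = effects,
        inclusionProb = drop(res$inclusion), pi = res$pi,
        beta = matrix(res$beta, ncol = 1), sigma2e = matrix(res$sigma2e),
        chain = list(nIter = nIter, burnIn = burnIn, seed = seed,
                     df = df, scale = scale),
        model = "BayesB")
}

#' Multi-trait BayesC-pi whole-genome regression
#'
#' Gibbs sampler for Y = X B + W A + E in which each marker has a single
#' shared inclusion indicator across the t traits (probability 1 - pi),
#' and included markers get a t-variate normal effect whose covariance
#' has an inverse-Wishart prior updated from the sampled effects; the
#' residual covariance across traits is likewise inverse-Wishart
#' updated.  With t = 1 this is single-trait BayesC with estimated pi.
#'
#' @param Y complete phenotype matrix (individuals x traits)
#' @param W marker score matrix
#' @param X fixed-effect design (default intercept)
#' @inheritParams fitBayesB
#' @return a [MarkerEffectFit-class] with t effect columns
#' @export
fitMultitraitBayesCpi <- function(Y, W, X = NULL, nIter = 12000,
                                  burnIn = 2000, piPrior = c(9, 1),
                                  seed = 1) {
    stopifnot(nIter > burnIn, burnIn >= 0)
    Y <- as.matrix(Y)
    if (anyNA(Y)) stop("phenotypes must be complete")
    W <- as.matrix(W)
    n <- nrow(Y)
    if (is.null(X)) X <- matrix(1, n, 1)
    X <- as.matrix(X)
    set.seed(seed)
    res <- bayescpi_gibbs(Y, X, W, as.integer(nIter), as.integer(burnIn),
                          piPrior[1], piPrior[2])
    if (!all(is.finite(res$effects)))
        stop("divergent chain: non-finite samples")
    dimnames(res$effects) <- list(colnames(W), colnames(Y))
    new("MarkerEffectFit", effects = res$effects,
        inclusionProb = drop(res$inclusion), pi = res$pi,
        beta = res$beta, sigma2e = res$R,
        chain = list(nIter = nIter, burnIn = burnIn, seed = seed),
        model = "BayesCpi")
}

#' Predict phenotypes from marker effects
#'
#' @param fit a [MarkerEffectFit-class]
#' @param W marker score matrix for the individuals to predict; columns
#'   must match the training markers (an error names any missing ones)
#' @param X fixed-effect design for those individuals (default intercept)
#' @return matrix of predictions (individuals x traits); a vector for
#'   single-trait fits
#' @export
predictMarkers <- function(fit, W, X = NULL) {
    stopifnot(is(fit, "MarkerEffectFit"))
    W <- as.matrix(W)
    train <- rownames(fit@effects)
    if (!is.null(train) && !is.null(colnames(W))) {
        missing <- setdiff(train, colnames(W))
        if (length(missing))
            stop("marker mismatch; missing from prediction set: ",
                 paste(head(missing, 10), collapse = ", "))
        W <- W[, train, drop = FALSE]
    }
    if (ncol(W) != nrow(fit@effects)) stop("marker count mismatch")
    if (is.null(X)) X <- matrix(1, nrow(W), 1)
    out <- as.matrix(X) %*% fit@beta + W %*% fit@effects
    if (ncol(out) == 1) drop(out) else out
}

#' Multi-trait GBLUP by EM-REML in the eigenbasis of G
#'
#' The stacked model vec(Y) ~ MVN(vec(XB), K (x) G + R (x) I_n) with K
#' the t x t genetic covariance and R the t x t residual covariance
#' ((x) the Kronecker product).  Rotating by the eigenvectors of G makes
#' the rows independent with covariance s_i K + R, and K and R are
#' estimated by iterated closed-form EM updates (with B re-estimated by
#' GLS each pass) until the relative change falls below `tol` or
#' `maxIter` is reached; non-convergence is flagged on the result, and
#' the last iterate returned.  Only complete cases are used.
#'
#' @param Y phenotype matrix (individuals x traits), t >= 2 supported
#'   (t = 1 works and reduces to the single-trait model)
#' @param G relationship matrix or [GRM-class]
#' @param X fixed-effect design (default intercept)
#' @param tol relative-change convergence tolerance
#' @param maxIter maximum EM iterations
#' @return a [MultiTraitFit-class]
#' @export
fitMultitraitGBLUP <- function(Y, G, X = NULL, tol = 1e-6, maxIter = 500) {
    if (is(G, "GRM")) G <- relMatrix(G)
    Y <- as.matrix(Y)
    n0 <- nrow(Y); t <- ncol(Y)
    if (is.null(X)) X <- matrix(1, n0, 1)
    X <- as.matrix(X)
    cc <- complete.cases(Y)
    Yc <- Y[cc, , drop = FALSE]; Xc <- X[cc, , drop = FALSE]
    Gc <- G[cc, cc, drop = FALSE]
    n <- nrow(Yc); p <- ncol(Xc)
    eg <- eigen(Gc, symmetric = TRUE)
    S <- pmax(eg$values, 0); U <- eg$vectors
    Ys <- crossprod(U, Yc); Xs <- crossprod(U, Xc)

    ols <- lm.fit(Xc, Yc)
    Vp <- cov(as.matrix(ols$residuals))
    ridge <- 1e-8 * mean(diag(Vp) + 1e-12)
    K <- Vp / 2 + diag(ridge, t); R <- Vp / 2 + diag(ridge, t)
    B <- matrix(0, p, t)
    Mrot <- matrix(0, n, t)
    converged <- FALSE
    iter <- 0L
    ## Each pass simultaneously diagonalizes (K, R): with
    ## T = Q' R^{-1/2} (Q the eigenvectors of R^{-1/2} K R^{-1/2}),
    ## every rotated row i has diagonal covariance s_i L + I, so the
    ## GLS update of B and the E-step are elementwise operations.
    for (iter in seq_len(maxIter)) {
        eR <- eigen(R, symmetric = TRUE)
        vR <- pmax(eR$values, 1e-12 * max(eR$values, 1e-300))
        Rih <- eR$vectors %*% (t(eR$vectors) / sqrt(vR))   # R^{-1/2}
        eM <- eigen(Rih %*% K %*% Rih, symmetric = TRUE)
        lam <- pmax(eM$values, 0)
        Tr <- crossprod(eM$vectors, Rih)
        Tinv <- solve(Tr)
        Yt <- Ys %*% t(Tr)
        D <- outer(S, lam) + 1                              # n x t
        Bt <- matrix(0, p, t)
        for (k in seq_len(t)) {
            w <- 1 / D[, k]
            Xw <- Xs * w
            Bt[, k] <- solve(crossprod(Xs, Xw), crossprod(Xw, Yt[, k]))
        }
        Rt <- Yt - Xs %*% Bt                                # rotated residuals
        SL <- outer(S, lam)
        LD <- t(lam * t(1 / D))                             # lam_k / D_ik
        Mt <- Rt * SL / D                                   # E[g] rotated
        Fac <- LD * sqrt(S)                                 # sqrt(s_i) lam_k / D_ik
        Ktil <- (crossprod(Rt * Fac) + diag(colSums(LD), t)) / n
        Rtil <- (crossprod(Rt - Mt) + diag(colSums(SL / D), t)) / n
        Knew <- Tinv %*% Ktil %*% t(Tinv)
        Rnew <- Tinv %*% Rtil %*% t(Tinv)
        Knew <- (Knew + t(Knew)) / 2
        Rnew <- (Rnew + t(Rnew)) / 2
        B <- Bt %*% t(Tinv)
        Mrot <- Mt %*% t(Tinv)
        delta <- max(abs(Knew - K), abs(Rnew - R)) /
                 max(abs(K), abs(R), 1e-12)
        K <- Knew; R <- Rnew
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("EM did not converge in ", maxIter,
                " iterations; returning last iterate")
    dK <- diag(K)
    corr <- K / sqrt(pmax(outer(dK, dK), 1e-300))
    corr[!is.finite(corr)] <- NA_real_
    h2 <- dK / (dK + diag(R))
    Uhat <- matrix(NA_real_, n0, t)
    Uhat[cc, ] <- U %*% Mrot
    dimnames(K) <- dimnames(R) <- dimnames(corr) <-
        list(colnames(Y), colnames(Y))
    new("MultiTraitFit", K = K, R = R, geneticCorr = corr,
        h2 = setNames(h2, colnames(Y)), B = B, U = Uhat,
        converged = converged, iterations = iter)
}
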