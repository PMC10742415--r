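# Independent oracles used by the tests.  These deliberately share no
# code with the package: the two-locus selfing oracle enumerates
# ordered haplotype pairs with explicit gamete-pattern sums, the
# three-locus oracle does the same over 8 haplotypes, and the ridge
# oracle is a direct penalized least-squares solve.

# haplotypes as allele vectors; gamete distribution of an ordered
# diplotype by enumerating the 2^L inheritance patterns
oracleGameteDist <- function(h1, h2, rvec) {
    L <- length(h1)
    haps <- list(h1, h2)
    out <- new.env(parent = emptyenv())
    addp <- function(key, p) {
        cur <- if (is.null(out[[key]])) 0 else out[[key]]
        out[[key]] <- cur + p
    }
    patterns <- expand.grid(rep(list(1:2), L))
    for (row in seq_len(nrow(patterns))) {
        s <- as.integer(patterns[row, ])
        g <- vapply(seq_len(L), function(l) haps[[s[l]]][l], numeric(1))
        p <- 0.5
        for (l in seq_len(L - 1))
            p <- p * if (s[l] == s[l + 1]) 1 - rvec[l] else rvec[l]
        addp(paste(g, collapse = ""), p)
    }
    keys <- ls(out)
    setNames(vapply(keys, function(k) out[[k]], numeric(1)), keys)
}

# distribution over ordered diplotypes (pairs of haplotype strings)
# in generation t of selfing from a given F1 pair
oracleSelfingDist <- function(f1a, f1b, rvec, t) {
    key <- function(a, b) paste(a, b, sep = "|")
    dist <- setNames(1, key(paste(f1a, collapse = ""),
                            paste(f1b, collapse = "")))
    for (gen in seq_len(t - 1)) {
        nxt <- new.env(parent = emptyenv())
        for (k in names(dist)) {
            p <- dist[[k]]
            hs <- strsplit(k, "|", fixed = TRUE)[[1]]
            h1 <- as.numeric(strsplit(hs[1], "")[[1]])
            h2 <- as.numeric(strsplit(hs[2], "")[[1]])
            gd <- oracleGameteDist(h1, h2, rvec)
            for (ga in names(gd)) for (gb in names(gd)) {
                kk <- key(ga, gb)
                cur <- if (is.null(nxt[[kk]])) 0 else nxt[[kk]]
                nxt[[kk]] <- cur + p * gd[[ga]] * gd[[gb]]
            }
        }
        ks <- ls(nxt)
        dist <- setNames(vapply(ks, function(k) nxt[[k]], numeric(1)), ks)
    }
    dist
}

# joint genotype-class table over L loci: array with dim rep(3, L)
oracleClassJoint <- function(rvec, t, f1a = NULL, f1b = NULL) {
    L <- length(rvec) + 1
    if (is.null(f1a)) f1a <- rep(0, L)
    if (is.null(f1b)) f1b <- rep(1, L)
    dist <- oracleSelfingDist(f1a, f1b, rvec, t)
    arr <- array(0, dim = rep(3, L))
    for (k in names(dist)) {
        hs <- strsplit(k, "|", fixed = TRUE)[[1]]
        h1 <- as.numeric(strsplit(hs[1], "")[[1]])
        h2 <- as.numeric(strsplit(hs[2], "")[[1]])
        idx <- matrix(h1 + h2 + 1, nrow = 1)
        arr[idx] <- arr[idx] + dist[[k]]
    }
    arr
}

# ridge-regression oracle: predictions of y from centered markers with
# explicit penalty; equivalent to GBLUP at matched lambda through the
# VanRaden normalization (see test)
oracleRidgePredict <- function(yc, Csc, penalty) {
    m <- ncol(Csc)
    alpha <- solve(crossprod(Csc) + diag(penalty, m), crossprod(Csc, yc))
    drop(Csc %*% alpha)
}

# direct single-marker regression LOD at a marker (2 df: additive +
# dominance), computed from lm residual sums of squares
oracleMarkerLOD <- function(y, score) {
    n <- length(y)
    f1 <- lm(y ~ score + I(score == 1))
    f0 <- lm(y ~ 1)
    (n / 2) * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
}
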