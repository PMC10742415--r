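## Composite interval mapping for F_t selfing populations.
##
## The scan is a Haley-Knott-style regression on conditional genotype
## expectations: at each grid position the phenotype is regressed on the
## expected additive dosage and the heterozygote probability given the
## flanking markers (computed from the exact F_t two-locus model), plus
## background cofactor markers, excluding cofactors within a window of
## the tested position.  LOD = (n/2) log10(RSS_null / RSS_full).

#' Conditional genotype-class probabilities on a scan grid
#'
#' At each grid position (default 1 cM step per chromosome) the
#' conditional probabilities of the three genotype classes are computed
#' per individual from the two flanking markers: the joint class tables
#' of (left flank, position) and (position, right flank) under the exact
#' F_t selfing model, with recombination fractions obtained from the
#' Kosambi inverse of the cM gaps, are combined and normalized over the
#' three classes.  An individual missing one flank falls back to
#' single-flank conditioning; missing both flanks, to the F_t marginal
#' ((1/2)^(t-1) heterozygotes, e.g. 3:2:3 at F3).  A position coinciding
#' with a scored marker puts probability 1 on the observed class.
#'
#' @param mm a [MarkerMatrix-class] (one population)
#' @param map a [LinkageMap-class] covering (a subset of) the markers
#' @param t generation index of the population
#' @param step grid step in cM
#' @return a [ScanGrid-class]
#' @export
conditionalProbs <- function(mm, map, t, step = 1) {
    stopifnot(is(mm, "MarkerMatrix"), is(map, "LinkageMap"), t >= 2)
    tab <- mapTable(map)
    tab <- tab[tab$marker %in% markerIds(mm), , drop = FALSE]
    sc <- genoScores(mm)
    n <- nrow(sc)
    marg <- selfingMarginal(t)
    posRows <- list(); P0 <- list(); P1 <- list(); P2 <- list()
    jointCache <- new.env(parent = emptyenv())
    jointAt <- function(d) {
        key <- sprintf("%.6f", d)
        if (is.null(jointCache[[key]]))
            jointCache[[key]] <- jointTable(selfingJoint(kosambiInv(d), t))
        jointCache[[key]]
    }
    for (ch in unique(tab$chrom)) {
        sub <- tab[tab$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$cM), , drop = FALSE]
        cm <- sub$cM
        g <- sc[, sub$marker, drop = FALSE]
        posGrid <- sort(unique(c(seq(0, max(cm), by = step), max(cm))))
        p0 <- matrix(0, n, length(posGrid))
        p1 <- matrix(0, n, length(posGrid))
        p2 <- matrix(0, n, length(posGrid))
        for (ip in seq_along(posGrid)) {
            pos <- posGrid[ip]
            li <- if (any(cm <= pos + 1e-9)) max(which(cm <= pos + 1e-9)) else NA
            ri <- if (any(cm > pos + 1e-9)) min(which(cm > pos + 1e-9)) else NA
            JL <- if (!is.na(li)) jointAt(pos - cm[li]) else NULL
            JR <- if (!is.na(ri)) jointAt(cm[ri] - pos) else NULL
            gL <- if (!is.na(li)) g[, li] else rep(NA_real_, n)
            gR <- if (!is.na(ri)) g[, ri] else rep(NA_real_, n)
            # 4 x 4 combos of (gL, gR) incl. missing -> probability triple
            keyL <- ifelse(is.na(gL), 3, gL)
            keyR <- ifelse(is.na(gR), 3, gR)
            for (a in 0:3) for (b in 0:3) {
                idx <- which(keyL == a & keyR == b)
                if (!length(idx)) next
                w <- if (a < 3 && b < 3) JL[a + 1L, ] * JR[, b + 1L] / marg
                     else if (a < 3) JL[a + 1L, ]
                     else if (b < 3) JR[, b + 1L]
                     else marg
                s <- sum(w)
                w <- if (s > 0) w / s else marg
                p0[idx, ip] <- w[1]; p1[idx, ip] <- w[2]; p2[idx, ip] <- w[3]
            }
        }
        posRows[[ch]] <- data.frame(chrom = ch, cM = posGrid)
        P0[[ch]] <- p0; P1[[ch]] <- p1; P2[[ch]] <- p2
    }
    positions <- do.call(rbind, posRows)
    rownames(positions) <- NULL
    new("ScanGrid", positions = positions,
        p0 = do.call(cbind, P0), p1 = do.call(cbind, P1),
        p2 = do.call(cbind, P2),
        individuals = rownames(sc), t = as.integer(t))
}

#' Forward stepwise selection of cofactor markers
#'
#' Repeatedly adds the marker giving the largest reduction in residual
#' sum of squares of the linear regression of the phenotype on the
#' markers already chosen (plus an intercept), until `k` markers are
#' selected.  Deterministic: ties are broken toward the first marker in
#' order.  Non-segregating markers are never chosen.
#'
#' @param mm a [MarkerMatrix-class]
#' @param phenotype numeric phenotype, one value per individual of `mm`
#' @param k number of cofactors
#' @return character vector of marker ids (length k)
#' @export
selectCofactors <- function(mm, phenotype, k = 5) {
    sc <- genoScores(mm)
    n <- nrow(sc)
    stopifnot(length(phenotype) == n, k < n - 2)
    if (k == 0) return(character())
    segregating <- apply(sc, 2, function(x) var(x, na.rm = TRUE) > 0)
    if (sum(segregating) < k)
        stop("fewer segregating markers (", sum(segregating), ") than k = ", k)
    X <- sc
    X[is.na(X)] <- 1  # neutral fill; cofactor selection assumes imputed data
    chosen <- character()
    Q <- matrix(1 / sqrt(n), n, 1)           # orthonormal basis: intercept
    yres <- phenotype - Q %*% crossprod(Q, phenotype)
    for (step in seq_len(k)) {
        Xp <- X - Q %*% crossprod(Q, X)
        ss <- colSums(Xp^2)
        gain <- drop(crossprod(Xp, yres))^2 / ifelse(ss > 1e-10, ss, Inf)
        gain[!segregating | colnames(X) %in% chosen] <- -Inf
        j <- which.max(gain)
        chosen <- c(chosen, colnames(X)[j])
        q <- Xp[, j] / sqrt(ss[j])
        Q <- cbind(Q, q)
        yres <- yres - q * sum(q * yres)
    }
    chosen
}

## orthonormal bases for the per-position full/null designs; collinear
## columns are dropped via rank-revealing QR
.qrBasis <- function(X) {
    dec <- qr(X)
    qr.Q(dec)[, seq_len(dec$rank), drop = FALSE]
}

# per-position designs for a scan: list of (Qfull, Qnull)
.scanEngine <- function(grid, cofScores, cofChrom, cofCM, windowCM) {
    pos <- grid@positions
    n <- length(grid@individuals)
    add <- grid@p1 + 2 * grid@p2
    dom <- grid@p1
    k <- if (is.null(cofScores)) 0L else ncol(cofScores)
    lapply(seq_len(nrow(pos)), function(ip) {
        keep <- if (k > 0)
            !(cofChrom == pos$chrom[ip] & abs(cofCM - pos$cM[ip]) <= windowCM)
        else logical(0)
        X0 <- cbind(rep(1, n),
                    if (any(keep)) cofScores[, keep, drop = FALSE])
        X1 <- cbind(X0, add[, ip], dom[, ip])
        list(Q0 = .qrBasis(X0), Q1 = .qrBasis(X1))
    })
}

# LOD profile for one or more phenotype columns; Y must be a matrix
.lodProfile <- function(engine, Y, cap = 50) {
    n <- nrow(Y)
    ytot <- colSums(Y^2)
    lods <- matrix(0, length(engine), ncol(Y))
    degen <- matrix(FALSE, length(engine), ncol(Y))
    for (ip in seq_along(engine)) {
        e <- engine[[ip]]
        rss0 <- pmax(ytot - colSums(crossprod(e$Q0, Y)^2), 0)
        rss1 <- pmax(ytot - colSums(crossprod(e$Q1, Y)^2), 0)
        bad <- rss1 <= 1e-10 * pmax(rss0, .Machine$double.eps)
        lod <- rep(cap, ncol(Y))
        lod[!bad] <- (n / 2) * log10(rss0[!bad] / rss1[!bad])
        lods[ip, ] <- pmin(pmax(lod, 0), cap)
        degen[ip, ] <- bad
    }
    list(lod = lods, degenerate = degen)
}

.cofData <- function(mm, map, cofactors) {
    if (!length(cofactors))
        return(list(scores = NULL, chrom = character(), cM = numeric()))
    sc <- genoScores(mm)[, cofactors, drop = FALSE]
    if (anyNA(sc))
        sc <- apply(sc, 2, function(x) {
            x[is.na(x)] <- mean(x, na.rm = TRUE); x })
    tab <- mapTable(map)
    idx <- match(cofactors, tab$marker)
    if (anyNA(idx)) stop("cofactors not on the map: ",
                         paste(cofactors[is.na(idx)], collapse = ", "))
    list(scores = sc, chrom = tab$chrom[idx], cM = tab$cM[idx])
}

#' Composite interval mapping scan
#'
#' At each grid position the phenotype is regressed on the expected
#' additive dosage E[score] and the heterozygote probability (2 df,
#' since selfing generations retain heterozygotes) from the
#' [ScanGrid-class], plus the cofactor marker scores — excluding
#' cofactors within `windowCM` of the position on the same chromosome.
#' The null model keeps the same included cofactors and drops the two
#' position terms.  LOD = (n/2) log10(RSS_null / RSS_full), capped at 50
#' with a degeneracy flag when the full model fits perfectly.  Collinear
#' design columns are dropped automatically.
#'
#' @param grid a [ScanGrid-class] from [conditionalProbs]
#' @param phenotype complete numeric phenotype (one per individual)
#' @param mm the [MarkerMatrix-class] (source of cofactor scores)
#' @param map the [LinkageMap-class] (cofactor positions)
#' @param cofactors marker ids used as cofactors (e.g. from
#'   [selectCofactors])
#' @param windowCM cofactor exclusion window in cM (default 10)
#' @return a [QTLScanResult-class] (no threshold yet; see
#'   [permutationThreshold])
#' @export
cimScan <- function(grid, phenotype, mm, map, cofactors = character(),
                    windowCM = 10) {
    stopifnot(is(grid, "ScanGrid"))
    if (anyNA(phenotype)) stop("phenotype must be complete for the scan")
    stopifnot(length(phenotype) == length(grid@individuals))
    cof <- .cofData(mm, map, cofactors)
    engine <- .scanEngine(grid, cof$scores, cof$chrom, cof$cM, windowCM)
    prof <- .lodProfile(engine, matrix(phenotype, ncol = 1))
    tab <- cbind(grid@positions, lod = prof$lod[, 1],
                 degenerate = prof$degenerate[, 1])
    new("QTLScanResult", table = tab, cofactors = cofactors,
        windowCM = windowCM, threshold = NA_real_, alpha = NA_real_,
        nPerm = 0L)
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Permutes the phenotype across individuals, rescans the genome, and
#' records the genome-wide maximum LOD of each permutation; the
#' threshold is the empirical (1 - alpha) quantile (type-7
#' interpolation).  By default cofactors are fixed at the set selected
#' from the observed phenotype and reused across permutations; the
#' strict mode (`reselectCofactors = TRUE`) re-selects them per
#' permutation.
#'
#' @inheritParams cimScan
#' @param nPerm number of permutations (>= 100; the threshold quantile
#'   is too unstable below that)
#' @param alpha genome-wide significance level
#' @param seed RNG seed for the permutations
#' @param reselectCofactors re-run cofactor selection per permutation
#' @param k cofactor count used when re-selecting
#' @return list with `threshold`, `alpha`, `nPerm`, `seed`, and the
#'   vector `maxLod` of permutation maxima
#' @export
permutationThreshold <- function(grid, phenotype, mm, map,
                                 cofactors = character(), windowCM = 10,
                                 nPerm = 1000, alpha = 0.05, seed = 1,
                                 reselectCofactors = FALSE, k = 5) {
    if (nPerm < 100) stop("nPerm must be >= 100")
    if (anyNA(phenotype)) stop("phenotype must be complete")
    set.seed(seed)
    n <- length(phenotype)
    if (reselectCofactors) {
        maxLod <- vapply(seq_len(nPerm), function(b) {
            yp <- phenotype[sample.int(n)]
            cf <- selectCofactors(mm, yp, k = k)
            max(scanTable(cimScan(grid, yp, mm, map, cf, windowCM))$lod)
        }, numeric(1))
    } else {
        cof <- .cofData(mm, map, cofactors)
        engine <- .scanEngine(grid, cof$scores, cof$chrom, cof$cM, windowCM)
        P <- vapply(seq_len(nPerm), function(b) phenotype[sample.int(n)],
                    numeric(n))
        prof <- .lodProfile(engine, P)
        maxLod <- apply(prof$lod, 2, max)
    }
    list(threshold = unname(quantile(maxLod, 1 - alpha, type = 7)),
         alpha = alpha, nPerm = as.integer(nPerm), seed = seed,
         maxLod = maxLod)
}

#' Full composite-interval-mapping protocol for one trait
#'
#' Convenience wrapper: selects `k` cofactors by forward stepwise
#' regression, builds the scan grid, runs the CIM scan, and attaches the
#' permutation threshold.
#'
#' @inheritParams cimScan
#' @inheritParams permutationThreshold
#' @param t generation index
#' @param step grid step (cM)
#' @param k number of cofactors (default 5, the protocol's setting)
#' @return a [QTLScanResult-class] with threshold set
#' @export
qtlScan <- function(mm, map, phenotype, t, step = 1, k = 5, windowCM = 10,
                    nPerm = 1000, alpha = 0.05, seed = 1) {
    cof <- selectCofactors(mm, phenotype, k = k)
    grid <- conditionalProbs(mm, map, t = t, step = step)
    scan <- cimScan(grid, phenotype, mm, map, cof, windowCM)
    perm <- permutationThreshold(grid, phenotype, mm, map, cof, windowCM,
                                 nPerm = nPerm, alpha = alpha, seed = seed)
    scan@threshold <- perm$threshold
    scan@alpha <- perm$alpha
    scan@nPerm <- perm$nPerm
    scan
}
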