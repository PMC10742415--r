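## Linkage-map construction for F_t selfing populations.
##
## The central object is the exact joint distribution of two linked
## marker classes in generation F_t of a selfing series.  Starting from
## the coupling F1 heterozygote AB/ab, every selfing generation draws two
## independent gametes per diplotype with per-meiosis recombination
## probability r.  The two-locus diplotype space has 10 unordered states,
## so the distribution is propagated exactly by a 10 x 10 transition
## matrix; genotype classes (0/1/2 per locus) are a marginalization of
## the diplotype distribution.

# haplotypes over two loci, allele 0 = reference parent:
#   1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1)
.hapAlleles <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))

# the 10 unordered diplotypes as index pairs
.diplotypes <- {
    idx <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
    idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# gamete distribution (over the 4 haplotypes) of each diplotype, given r
.gameteDist <- function(r) {
    out <- matrix(0, nrow(.diplotypes), 4)
    for (d in seq_len(nrow(.diplotypes))) {
        i <- .diplotypes[d, 1]; j <- .diplotypes[d, 2]
        x1 <- .hapAlleles[i, ]; x2 <- .hapAlleles[j, ]
        par1 <- i
        par2 <- j
        rec1 <- which(.hapAlleles[, 1] == x1[1] & .hapAlleles[, 2] == x2[2])
        rec2 <- which(.hapAlleles[, 1] == x2[1] & .hapAlleles[, 2] == x1[2])
        out[d, par1] <- out[d, par1] + (1 - r) / 2
        out[d, par2] <- out[d, par2] + (1 - r) / 2
        out[d, rec1] <- out[d, rec1] + r / 2
        out[d, rec2] <- out[d, rec2] + r / 2
    }
    out
}

# map an unordered haplotype pair (i <= j) to its diplotype index
.dipIndex <- local({
    m <- matrix(0L, 4, 4)
    for (d in seq_len(nrow(.diplotypes)))
        m[.diplotypes[d, 1], .diplotypes[d, 2]] <-
            m[.diplotypes[d, 2], .diplotypes[d, 1]] <- d
    m
})

# selfing transition matrix on the 10 diplotype states
.selfingTransition <- function(r) {
    gam <- .gameteDist(r)
    T <- matrix(0, 10, 10)
    for (d in seq_len(10)) {
        pg <- gam[d, ]
        for (i in 1:4) for (j in i:4) {
            p <- if (i == j) pg[i]^2 else 2 * pg[i] * pg[j]
            T[d, .dipIndex[i, j]] <- T[d, .dipIndex[i, j]] + p
        }
    }
    T
}

#' Exact F_t two-locus genotype-class distribution under selfing
#'
#' Computes the joint probability of the genotype classes (0 = homozygous
#' reference parent, 1 = heterozygous, 2 = homozygous other parent) at
#' two linked loci in generation F_t of repeated selfing from the
#' coupling F1 heterozygote, with per-meiosis recombination fraction `r`.
#' At F3 the single-locus marginal is the familiar 3:2:3 class ratio.
#'
#' The class-level table is symmetric in coupling vs repulsion phase:
#' swapping which parent is scored 0 at one locus permutes rows/columns
#' but the likelihood built from unphased 0/1/2 scores cannot separate
#' the two phases.  All downstream estimation is therefore phase-unaware.
#'
#' @param r recombination fraction, in [0, 0.5]
#' @param t generation index (2 = F2, 3 = F3, 4 = F4, ...)
#' @return a [SelfingJoint-class]
#' @examples
#' jointTable(selfingJoint(0, 3))        # diagonal 3/8, 2/8, 3/8
#' jointTable(selfingJoint(0.5, 3))      # independent 3:2:3 marginals
#' @export
selfingJoint <- function(r, t) {
    if (!is.numeric(r) || length(r) != 1 || r < 0 || r > 0.5)
        stop("r must be a single value in [0, 0.5]")
    t <- as.integer(t)
    if (t < 2L) stop("t must be >= 2 (F2 or later)")
    new("SelfingJoint", r = r, t = t, table = .selfingTableRaw(r, t))
}

## exact F_t table started from the coupling (AB/ab) or repulsion
## (Ab/aB) F1 heterozygote; the repulsion start is what the data look
## like when the 0/2 coding of one locus is swapped
.selfingTableRaw <- function(r, t, phase = c("coupling", "repulsion")) {
    phase <- match.arg(phase)
    p <- numeric(10)
    start <- if (phase == "coupling") .dipIndex[1, 4] else .dipIndex[2, 3]
    p[start] <- 1
    T <- .selfingTransition(r)
    for (gen in seq_len(t - 1L)) p <- as.numeric(p %*% T)
    tab <- matrix(0, 3, 3, dimnames = list(A = 0:2, B = 0:2))
    for (d in seq_len(10)) {
        i <- .diplotypes[d, 1]; j <- .diplotypes[d, 2]
        ga <- .hapAlleles[i, 1] + .hapAlleles[j, 1]
        gb <- .hapAlleles[i, 2] + .hapAlleles[j, 2]
        tab[ga + 1L, gb + 1L] <- tab[ga + 1L, gb + 1L] + p[d]
    }
    tab
}

# grid tables reused across pairs (keyed by generation and phase)
.jointGridCache <- new.env(parent = emptyenv())
.jointGridTables <- function(t, grid, phase) {
    key <- paste0(t, "_", phase)
    if (is.null(.jointGridCache[[key]]))
        .jointGridCache[[key]] <- lapply(grid, .selfingTableRaw, t = t,
                                         phase = phase)
    .jointGridCache[[key]]
}

#' Single-locus genotype-class marginal in generation F_t
#'
#' Heterozygosity halves each selfing generation: the heterozygote
#' fraction at F_t is (1/2)^(t-1), the two homozygote classes share the
#' rest equally.  At F3 this is the 3:2:3 ratio.
#'
#' @param t generation index (>= 2)
#' @return probability vector over classes (0, 1, 2)
#' @export
selfingMarginal <- function(t) {
    t <- as.integer(t)
    if (t < 2L) stop("t must be >= 2")
    het <- 0.5^(t - 1L)
    c(`0` = (1 - het) / 2, `1` = het, `2` = (1 - het) / 2)
}

#' Maximum-likelihood recombination fraction between two markers
#'
#' Maximizes the log-likelihood of the observed pairs of 0/1/2 genotype
#' classes under the exact F_t selfing model ([selfingJoint]).  A coarse
#' grid (step 0.01) locates the optimum, which is then refined by
#' bounded scalar optimization.  Only individuals with both loci
#' non-missing are informative.
#'
#' The 0/1/2 classes do not reveal linkage phase: recoding which parent
#' scores 0 at one locus turns coupling data into repulsion data.  The
#' estimator is therefore phase-unaware: it maximizes the likelihood
#' jointly over r and the F1 phase (coupling AB/ab vs repulsion Ab/aB
#' start of the selfing recursion), so the estimate is exactly invariant
#' to how either locus is coded.
#'
#' @param scoresA,scoresB genotype scores (0/1/2, NA allowed) at the two
#'   loci, one entry per individual
#' @param t generation index of the population
#' @param phase "unaware" (default) maximizes over both phases;
#'   "coupling" restricts to the coupling model — appropriate inside
#'   [buildMap], where all scores share one reference parent and
#'   adjacent pairs are coupling by construction
#' @return a [RecombEstimate-class]
#' @export
estimateRecombination <- function(scoresA, scoresB, t,
                                  phase = c("unaware", "coupling")) {
    phase <- match.arg(phase)
    phases <- if (phase == "coupling") "coupling"
              else c("coupling", "repulsion")
    stopifnot(length(scoresA) == length(scoresB))
    keep <- !is.na(scoresA) & !is.na(scoresB)
    n <- sum(keep)
    if (n < 2L) stop("need at least 2 informative individuals")
    counts <- table(factor(scoresA[keep], levels = 0:2),
                    factor(scoresB[keep], levels = 0:2))
    counts <- matrix(as.numeric(counts), 3, 3)
    llOf <- function(tab) {
        lt <- ifelse(counts > 0, log(pmax(tab, 1e-300)), 0)
        sum(counts * lt)
    }
    grid <- seq(0, 0.5, by = 0.01)
    bestR <- NA_real_; bestLL <- -Inf
    for (phase in phases) {
        negll <- function(r) -llOf(.selfingTableRaw(r, t, phase))
        vals <- -vapply(.jointGridTables(t, grid, phase), llOf, numeric(1))
        best <- which.min(vals)
        lo <- grid[max(1L, best - 1L)]
        hi <- grid[min(length(grid), best + 1L)]
        opt <- optimize(negll, c(lo, hi), tol = 1e-6)
        rhat <- opt$minimum
        ll <- -opt$objective
        # the bounded search can sit just inside an end-point; keep the
        # grid end-point when it is at least as good
        for (rEdge in c(lo, hi, grid[best])) {
            if (negll(rEdge) <= -ll + 1e-12) { rhat <- rEdge; ll <- -negll(rEdge) }
        }
        if (ll > bestLL) { bestLL <- ll; bestR <- rhat }
    }
    new("RecombEstimate", rHat = bestR, logLik = bestLL,
        nInformative = as.integer(n))
}

#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a recombination fraction to map distance,
#' d = 25 * log((1 + 2r) / (1 - 2r)) centiMorgans; `kosambiInv()` is the
#' closed-form inverse r = tanh(d / 50) / 2.  The map function partially
#' accounts for crossover interference.
#'
#' @param r recombination fraction in [0, 0.5)
#' @param d map distance in centiMorgans (>= 0)
#' @return `kosambi()`: distance in cM; `kosambiInv()`: recombination
#'   fraction.
#' @examples
#' kosambi(0.25)            # 25 * log(3) ~ 27.465
#' kosambiInv(kosambi(0.3)) # 0.3
#' @export
kosambi <- function(r) {
    if (any(r < 0 | r >= 0.5))
        stop("r must lie in [0, 0.5); pairs at free recombination are excluded upstream")
    25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambiInv <- function(d) {
    if (any(d < 0)) stop("d must be >= 0")
    tanh(d / 50) / 2
}

#' Haldane map function and its inverse
#'
#' Interference-free map function: d = -50 * log(1 - 2r); inverse
#' r = (1 - exp(-2 d / 100)) / 2.  This is the generative model of the
#' simulator's crossover process.
#'
#' @inheritParams kosambi
#' @export
haldane <- function(r) {
    if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
    -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @export
haldaneInv <- function(d) {
    if (any(d < 0)) stop("d must be >= 0")
    (1 - exp(-d / 50)) / 2
}

#' Build a linkage map from one population
#'
#' Walks along the declared marker order within each chromosome (the
#' order is fixed to the reference order carried by the MarkerMatrix, no
#' reordering is attempted), estimates the adjacent-pair recombination
#' fraction by [estimateRecombination] under the coupling model (scores
#' are all coded against one reference parent, so adjacent pairs are in
#' coupling by construction; a marker whose coding is inconsistent shows
#' up as apparent repulsion, drives the coupling estimate to the 0.5
#' boundary and is dropped), removes markers whose fraction with the
#' previous retained marker exceeds `rMax`, and accumulates Kosambi
#' distances from each chromosome's first retained marker.
#'
#' @param mm a [MarkerMatrix-class] for a single population
#' @param t generation index of the population (the map model)
#' @param rMax adjacent recombination fractions above this value drop
#'   the offending marker (default 0.499)
#' @return a [LinkageMap-class]; dropped markers are recorded
#' @export
buildMap <- function(mm, t, rMax = 0.499) {
    stopifnot(is(mm, "MarkerMatrix"))
    info <- markerInfo(mm)
    sc <- genoScores(mm)
    dropped <- character()
    rows <- list()
    for (ch in unique(info$chrom)) {
        ids <- rownames(info)[info$chrom == ch]
        if (length(ids) == 1L) {
            warning("chromosome ", ch, " has a single marker; map fixed at 0 cM")
            rows[[ch]] <- data.frame(marker = ids, chrom = ch, cM = 0)
            next
        }
        keep <- ids[1]
        cum <- 0
        last <- ids[1]
        pos <- c(0)
        for (id in ids[-1]) {
            est <- estimateRecombination(sc[, last], sc[, id], t,
                                         phase = "coupling")
            if (rHat(est) > rMax) {
                dropped <- c(dropped, id)
                next
            }
            cum <- cum + kosambi(min(rHat(est), rMax))
            keep <- c(keep, id)
            pos <- c(pos, cum)
            last <- id
        }
        rows[[ch]] <- data.frame(marker = keep, chrom = ch, cM = pos)
    }
    positions <- do.call(rbind, rows)
    rownames(positions) <- NULL
    if (length(dropped))
        message("buildMap: dropped ", length(dropped),
                " marker(s) with adjacent r > ", rMax, ": ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else "")
    new("LinkageMap", positions = positions, dropped = dropped,
        generation = as.integer(t))
}

#' Linkage map from marker metadata
#'
#' Builds a [LinkageMap-class] directly from the cM positions carried in
#' a MarkerMatrix's marker metadata (e.g. the known map of a simulated
#' data set), shifting each chromosome so its first marker sits at 0 cM.
#'
#' @param mm a [MarkerMatrix-class] with `posCM` metadata
#' @return a [LinkageMap-class]
#' @export
mapFromMarkerInfo <- function(mm) {
    info <- markerInfo(mm)
    if (anyNA(info$posCM)) stop("marker metadata has no cM positions")
    pos <- data.frame(marker = rownames(info), chrom = info$chrom,
                      cM = info$posCM)
    pos <- pos[order(pos$chrom, pos$cM), ]
    for (ch in unique(pos$chrom)) {
        i <- pos$chrom == ch
        pos$cM[i] <- pos$cM[i] - min(pos$cM[i])
    }
    rownames(pos) <- NULL
    new("LinkageMap", positions = pos, dropped = character(),
        generation = NA_integer_)
}

#' Consensus linkage map across populations by loess smoothing
#'
#' Pools (shared marker rank, population cM) points from all
#' per-population maps on each chromosome; the shared rank is the
#' marker's index in the union order (populations may carry different
#' marker subsets).  The consensus position at each rank is the mean of
#' the population positions there, plus a locally weighted regression
#' (loess) of the pooled deviations from those means on rank — the
#' smoothing term irons out rank-local jumps where the maps disagree or
#' where a marker is present in only some populations, and vanishes
#' when the maps coincide.  Smoothed positions are made monotone
#' non-decreasing by pool-adjacent-violators ([stats::isoreg]) and
#' shifted so each chromosome starts at 0 cM.
#'
#' @param maps list of [LinkageMap-class] objects sharing the reference
#'   marker order (marker subsets may differ)
#' @param span loess span (the fraction of points in each local fit)
#' @return a consensus [LinkageMap-class] over the union of markers
#' @export
consensusMap <- function(maps, span = 0.3) {
    stopifnot(length(maps) >= 1L, all(vapply(maps, is, logical(1), "LinkageMap")))
    tabs <- lapply(maps, mapTable)
    chroms <- unique(unlist(lapply(tabs, function(x) x$chrom)))
    rows <- list()
    for (ch in chroms) {
        subs <- lapply(tabs, function(x) x[x$chrom == ch, , drop = FALSE])
        subs <- subs[vapply(subs, nrow, integer(1)) > 0L]
        if (!length(subs)) next
        # union order: interleave by first appearance; per-population maps
        # are subsets of one reference order, so ranking by mean relative
        # position preserves it
        union <- unique(unlist(lapply(subs, function(x) x$marker)))
        rank <- setNames(seq_along(union), union)
        pts <- do.call(rbind, lapply(subs, function(x)
            data.frame(rank = rank[x$marker], cM = x$cM)))
        if (length(union) < 2L) {
            rows[[ch]] <- data.frame(marker = union, chrom = ch, cM = 0)
            next
        }
        rankMean <- vapply(seq_along(union), function(r)
            mean(pts$cM[pts$rank == r]), numeric(1))
        pts$dev <- pts$cM - rankMean[pts$rank]
        smooth <- rep(0, length(union))
        if (max(abs(pts$dev)) > 1e-12) {
            smooth <- tryCatch({
                lo <- suppressWarnings(
                    loess(dev ~ rank, data = pts, span = span, degree = 1,
                          control = loess.control(surface = "direct")))
                predict(lo, newdata = data.frame(rank = seq_along(union)))
            }, error = function(e) rep(0, length(union)))
            if (anyNA(smooth)) smooth[is.na(smooth)] <- 0
        }
        mono <- isoreg(seq_along(union), rankMean + smooth)$yf
        mono <- mono - mono[1]
        rows[[ch]] <- data.frame(marker = union, chrom = ch, cM = mono)
    }
    positions <- do.call(rbind, rows)
    rownames(positions) <- NULL
    new("LinkageMap", positions = positions, dropped = character(),
        generation = NA_integer_)
}

#' @importFrom stats loess.control approx
NULL
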