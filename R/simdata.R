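## Synthetic breeding populations with known ground truth.
##
## The generator emulates a medicinal-plant breeding programme of
## biparental crosses between one recurrent (red) parent and several
## donor (green) parents, advanced by repeated selfing with selection:
## F2 lines grown, a subset selected and selfed (several seeds per line)
## to give the F3, an F3 subset selected (half among lines grown in the
## field, half among those not grown) and selfed again to give the F4.
## Crossovers follow an interference-free Poisson process (Haldane model).

#' Construct a GenomeSpec
#'
#' @param nChrom number of chromosomes
#' @param chromLengths chromosome lengths in cM (recycled to `nChrom`)
#' @param markersPerChrom markers per chromosome, placed equidistantly
#'   over (0, length] unless `markerPos` is given
#' @param markerPos optional list of marker position vectors (cM), one
#'   per chromosome, strictly increasing
#' @return a [GenomeSpec-class]
#' @export
genomeSpec <- function(nChrom, chromLengths, markersPerChrom = NULL,
                       markerPos = NULL) {
    nChrom <- as.integer(nChrom)
    chromLengths <- rep_len(as.numeric(chromLengths), nChrom)
    if (is.null(markerPos)) {
        if (is.null(markersPerChrom))
            stop("give markersPerChrom or markerPos")
        markersPerChrom <- rep_len(as.integer(markersPerChrom), nChrom)
        markerPos <- lapply(seq_len(nChrom), function(i)
            seq(0, chromLengths[i], length.out = markersPerChrom[i] + 1L)[-1L] -
                chromLengths[i] / (2 * markersPerChrom[i]))
    }
    new("GenomeSpec", nChrom = nChrom, chromLengths = chromLengths,
        markerPos = markerPos)
}

#' A perilla-like default genome
#'
#' Twenty chromosomes (the perilla haploid linkage-group number; the
#' allotetraploid genotypes behave as diploid-coded biallelic markers),
#' each 70 cM with 30 equidistant markers, for 600 markers genome-wide —
#' of the order of the marker counts retained per population after MAF
#' filtering in ddRAD-based perilla panels.
#'
#' @param nChrom,chromLength,markersPerChrom override the preset
#' @return a [GenomeSpec-class]
#' @export
perillaGenome <- function(nChrom = 20, chromLength = 70, markersPerChrom = 30)
    genomeSpec(nChrom, chromLength, markersPerChrom)

#' Construct a BreedingScheme
#'
#' Defaults reproduce the programme scheme: 200 F2 lines, 100 selected,
#' 3 seeds per line, 50 + 50 F3 lines selected among grown/ungrown.
#'
#' @param f2Lines,f2Selected,seedsPerLine,f3SelectedGrown,f3SelectedUngrown
#'   counts, see [BreedingScheme-class]
#' @param selectionMode "random" (default; the programme selected partly
#'   to maintain diversity, without a stated criterion) or "truncation"
#' @return a [BreedingScheme-class]
#' @export
breedingScheme <- function(f2Lines = 200, f2Selected = 100, seedsPerLine = 3,
                           f3SelectedGrown = 50, f3SelectedUngrown = 50,
                           selectionMode = c("random", "truncation")) {
    new("BreedingScheme", f2Lines = as.integer(f2Lines),
        f2Selected = as.integer(f2Selected),
        seedsPerLine = as.integer(seedsPerLine),
        f3SelectedGrown = as.integer(f3SelectedGrown),
        f3SelectedUngrown = as.integer(f3SelectedUngrown),
        selectionMode = match.arg(selectionMode))
}

#' Construct a TraitArchitecture
#'
#' @param qtl data.frame with columns `chrom`, `posCM`, `effect` (additive
#'   effect in trait units per allele substitution), or NULL for a purely
#'   polygenic trait
#' @param nPolygenes number of small-effect loci (attached to randomly
#'   chosen markers)
#' @param polygeneSD standard deviation of polygene effects (trait units)
#' @param targetH2 target genomic heritability in [0, 1]
#' @param presenceLocus optional c(chrom, posCM, abolishingScore): when an
#'   individual is homozygous for the designated parent (score 0 or 2) at
#'   this locus its genetic value is set to 0 before noise — the
#'   presence/absence architecture seen for perillaldehyde, where one
#'   parental homozygote abolishes the compound
#' @return a [TraitArchitecture-class]
#' @export
traitArchitecture <- function(qtl = NULL, nPolygenes = 0, polygeneSD = 0,
                              targetH2 = 0.5, presenceLocus = numeric()) {
    if (is.null(qtl))
        qtl <- data.frame(chrom = integer(), posCM = numeric(),
                          effect = numeric())
    new("TraitArchitecture", nQTLLarge = nrow(qtl),
        qtlChrom = as.integer(qtl$chrom), qtlPos = as.numeric(qtl$posCM),
        qtlEffect = as.numeric(qtl$effect),
        nPolygenes = as.integer(nPolygenes),
        polygeneSD = as.numeric(polygeneSD),
        targetH2 = as.numeric(targetH2),
        presenceLocus = as.numeric(presenceLocus))
}

#' Construct a MultiTraitSpec
#'
#' @param architectures list of [TraitArchitecture-class] (one per trait)
#' @param geneticCorr t x t correlation matrix for the shared polygenic
#'   effects (default identity)
#' @param traitNames trait labels
#' @return a [MultiTraitSpec-class]
#' @export
multiTraitSpec <- function(architectures, geneticCorr = NULL,
                           traitNames = NULL) {
    t <- length(architectures)
    if (is.null(geneticCorr)) geneticCorr <- diag(t)
    if (is.null(traitNames)) traitNames <- sprintf("trait%d", seq_len(t))
    new("MultiTraitSpec", architectures = architectures,
        geneticCorr = as.matrix(geneticCorr), traitNames = traitNames)
}

## ---------------------------------------------------------------------------
## Gametes and generations
## ---------------------------------------------------------------------------

# chromosome index per marker, and marker index ranges per chromosome
.chromIndex <- function(spec) {
    rep(seq_len(spec@nChrom), vapply(spec@markerPos, length, integer(1)))
}

#' Fully inbred parents
#'
#' Parent 1 is the reference parent (allele 0, genotype score 0 at every
#' marker).  Parent 2 carries the alternative allele at every marker, so
#' every marker segregates in the designated cross pair.  Further parents
#' carry the alternative allele at a random fraction
#' `segregatingFraction` of markers, so different crosses segregate at
#' different (overlapping) marker subsets — the situation that makes
#' per-population MAF filtering retain different marker counts.
#'
#' @param spec a [GenomeSpec-class]
#' @param nParents number of parents (>= 2)
#' @param seed RNG seed
#' @param segregatingFraction fraction of markers at which parents 3+
#'   differ from the reference parent
#' @return matrix (nParents x markers) of haplotype alleles, 0 =
#'   reference allele; each parent's diplotype is two copies of its row
#' @export
makeParents <- function(spec, nParents = 2, seed = NULL,
                        segregatingFraction = 1) {
    stopifnot(is(spec, "GenomeSpec"), nParents >= 2)
    if (!is.null(seed)) set.seed(seed)
    m <- sum(vapply(spec@markerPos, length, integer(1)))
    parents <- matrix(0L, nParents, m)
    parents[2, ] <- 1L
    if (nParents > 2) {
        for (k in 3:nParents) {
            sel <- sample.int(m, size = round(segregatingFraction * m))
            parents[k, sel] <- 1L
        }
    }
    rownames(parents) <- c("P1", sprintf("P%d", seq_len(nParents - 1L) + 1L))
    colnames(parents) <- .markerNames(spec)
    parents
}

.markerNames <- function(spec) {
    unlist(lapply(seq_len(spec@nChrom), function(i)
        sprintf("c%02dm%03d", i, seq_along(spec@markerPos[[i]]))))
}

#' One meiosis: a gamete haplotype from a diplotype
#'
#' Crossovers per chromosome are drawn as a Poisson count with mean equal
#' to the chromosome length in Morgans, with positions uniform along the
#' chromosome (no interference); the gamete alternates between the two
#' parental haplotypes at the crossover points, starting from either with
#' probability 1/2.  Recombination fractions therefore follow the Haldane
#' map function of the inter-marker distance.
#'
#' @param h1,h2 the two haplotypes (allele vectors over all markers, in
#'   `spec` order)
#' @param spec a [GenomeSpec-class]
#' @param seed optional RNG seed
#' @return a gamete haplotype (integer vector)
#' @export
meiosis <- function(h1, h2, spec, seed = NULL) {
    m <- sum(vapply(spec@markerPos, length, integer(1)))
    if (length(h1) != m || length(h2) != m)
        stop("haplotype length does not match the genome spec")
    if (!is.null(seed)) set.seed(seed)
    gam <- integer(m)
    off <- 0L
    for (i in seq_len(spec@nChrom)) {
        p <- spec@markerPos[[i]]
        L <- spec@chromLengths[i]
        k <- rpois(1L, L / 100)
        xo <- sort(runif(k, 0, L))
        start <- rbinom(1L, 1L, 0.5)
        phase <- (start + findInterval(p, xo)) %% 2L
        idx <- off + seq_along(p)
        gam[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
        off <- off + length(p)
    }
    gam
}

# vectorized meiosis for a whole population: one gamete per row of the
# parental haplotype matrices (same crossover model as meiosis())
.batchMeiosis <- function(P1, P2, spec) {
    n <- nrow(P1)
    gam <- P1
    off <- 0L
    for (i in seq_len(spec@nChrom)) {
        p <- spec@markerPos[[i]]
        mc <- length(p)
        idx <- off + seq_len(mc)
        L <- spec@chromLengths[i]
        k <- rpois(n, L / 100)
        start <- sample.int(2L, n, replace = TRUE) - 1L
        phase <- matrix(start, n, mc)
        for (j in which(k > 0L)) {
            xo <- sort(runif(k[j], 0, L))
            phase[j, ] <- (start[j] + findInterval(p, xo)) %% 2L
        }
        sel <- phase == 1L
        blk <- P1[, idx, drop = FALSE]
        blk[sel] <- P2[, idx, drop = FALSE][sel]
        gam[, idx] <- blk
        off <- off + mc
    }
    gam
}

# self a population: two independent gametes per row
.selfPopulation <- function(pop, rows, spec) {
    P1 <- pop$h1[rows, , drop = FALSE]
    P2 <- pop$h2[rows, , drop = FALSE]
    list(h1 = .batchMeiosis(P1, P2, spec),
         h2 = .batchMeiosis(P1, P2, spec))
}

#' Genotype scores from a simulated population
#'
#' @param pop a generation entry of [advanceGenerations] output
#' @return matrix of 0/1/2 scores (count of non-reference alleles),
#'   individuals x markers
#' @export
popScores <- function(pop) {
    sc <- pop$h1 + pop$h2
    rownames(sc) <- pop$ids
    sc
}

#' Advance a biparental cross through the selfing breeding scheme
#'
#' Produces F1 (the cross), F2 (selfed F1 lines), F3 (selected F2 lines
#' selfed, several seeds per line) and F4 (selected F3 lines selfed),
#' recording the pedigree (parent line of every individual) and, for the
#' F3, a grown-in-field flag used by the split selection rule.
#'
#' Selection is random by default; with `selectionMode = "truncation"` a
#' `truncationTrait` architecture must be supplied and lines with the
#' highest true genetic value are kept.
#'
#' @param parentA,parentB parental haplotypes (rows of [makeParents])
#' @param scheme a [BreedingScheme-class]
#' @param spec a [GenomeSpec-class]
#' @param seed RNG seed
#' @param truncationTrait optional [TraitArchitecture-class] used when
#'   the scheme selects by truncation
#' @param lastGeneration stop after this generation ("F4" default;
#'   "F3" skips the final selfing round)
#' @return list with elements `F1`, `F2`, `F3` (and `F4` unless stopped
#'   earlier), each a list with haplotype matrices `h1`, `h2`,
#'   individual `ids` and a `pedigree` data.frame
#' @export
advanceGenerations <- function(parentA, parentB, scheme, spec, seed = NULL,
                               truncationTrait = NULL,
                               lastGeneration = c("F4", "F3")) {
    lastGeneration <- match.arg(lastGeneration)
    stopifnot(is(scheme, "BreedingScheme"), is(spec, "GenomeSpec"))
    if (!is.null(seed)) set.seed(seed)
    if (scheme@selectionMode == "truncation" && is.null(truncationTrait))
        stop("truncation selection needs a truncationTrait architecture")
    m <- length(parentA)

    f1 <- list(h1 = matrix(as.integer(parentA), 1), h2 = matrix(as.integer(parentB), 1),
               ids = "F1_1",
               pedigree = data.frame(id = "F1_1", parent = NA_character_,
                                     grown = NA))

    # F2: selfed F1 lines
    f2 <- .selfPopulation(f1, rep(1L, scheme@f2Lines), spec)
    f2$ids <- sprintf("F2_%03d", seq_len(scheme@f2Lines))
    f2$pedigree <- data.frame(id = f2$ids, parent = "F1_1", grown = TRUE)

    selVal <- function(pop) {
        if (scheme@selectionMode == "random")
            return(NULL)
        g <- .geneticValuesOne(pop$h1 + pop$h2, truncationTrait, spec)
        g
    }
    pick <- function(n, k, values) {
        if (is.null(values)) sample.int(n, k)
        else order(values, decreasing = TRUE)[seq_len(k)]
    }

    selF2 <- sort(pick(scheme@f2Lines, scheme@f2Selected, selVal(f2)))

    # F3: seedsPerLine offspring per selected F2 line
    f3rows <- rep(selF2, each = scheme@seedsPerLine)
    f3par <- f2$ids[f3rows]
    f3 <- .selfPopulation(f2, f3rows, spec)
    nF3 <- length(f3rows)
    f3$ids <- sprintf("F3_%03d", seq_len(nF3))
    grown <- rep(FALSE, nF3)
    grown[sample.int(nF3, ceiling(nF3 / 2))] <- TRUE
    f3$pedigree <- data.frame(id = f3$ids, parent = f3par, grown = grown)
    if (lastGeneration == "F3")
        return(list(F1 = f1, F2 = f2, F3 = f3))

    # split selection: part among grown lines, part among ungrown
    vals <- selVal(f3)
    gIdx <- which(grown); uIdx <- which(!grown)
    if (scheme@f3SelectedGrown > length(gIdx) ||
        scheme@f3SelectedUngrown > length(uIdx))
        stop("F3 selection counts exceed the grown/ungrown line counts")
    selG <- gIdx[pick(length(gIdx), scheme@f3SelectedGrown, vals[gIdx])]
    selU <- uIdx[pick(length(uIdx), scheme@f3SelectedUngrown, vals[uIdx])]
    selF3 <- sort(c(selG, selU))

    # F4: seedsPerLine offspring per selected F3 line
    f4rows <- rep(selF3, each = scheme@seedsPerLine)
    f4par <- f3$ids[f4rows]
    f4 <- .selfPopulation(f3, f4rows, spec)
    f4$ids <- sprintf("F4_%03d", seq_along(f4rows))
    f4$pedigree <- data.frame(id = f4$ids, parent = f4par, grown = TRUE)

    list(F1 = f1, F2 = f2, F3 = f3, F4 = f4)
}

## ---------------------------------------------------------------------------
## Phenotypes
## ---------------------------------------------------------------------------

# nearest-marker index for a (chrom, cM) position
.nearestMarker <- function(spec, chrom, posCM) {
    stopifnot(chrom >= 1, chrom <= spec@nChrom)
    p <- spec@markerPos[[chrom]]
    off <- if (chrom > 1)
        sum(vapply(spec@markerPos[seq_len(chrom - 1)], length, integer(1)))
    else 0L
    off + which.min(abs(p - posCM))
}

# genetic values of one architecture ignoring polygenes-correlation
# machinery (used for truncation selection)
.geneticValuesOne <- function(scores, arch, spec) {
    g <- numeric(nrow(scores))
    if (arch@nQTLLarge > 0) {
        for (q in seq_len(arch@nQTLLarge)) {
            j <- .nearestMarker(spec, arch@qtlChrom[q], arch@qtlPos[q])
            g <- g + arch@qtlEffect[q] * (scores[, j] - 1)
        }
    }
    g
}

#' Simulate correlated multi-trait phenotypes on a population
#'
#' Each trait's genetic value is the sum of its large-QTL effects
#' (attached to the marker nearest the stated position) and shared
#' polygenic effects.  Polygene effect vectors across traits are drawn
#' jointly from a multivariate normal with covariance
#' `D^{1/2} C D^{1/2}` (C the genetic correlation matrix, D the per-trait
#' polygene variances), so the true genetic values realize the requested
#' genetic correlations.  If a presence locus is set, individuals
#' homozygous for the designated parent there have their genetic value
#' zeroed before noise.  Residual noise variance is set from the realized
#' genetic variance so that the realized heritability matches
#' `targetH2`; with `targetH2 = 0` the genetic values are zeroed and the
#' phenotype is pure noise, with `targetH2 = 1` the phenotype equals the
#' genetic value.
#'
#' @param scores genotype score matrix (individuals x markers) or a
#'   [MarkerMatrix-class]
#' @param mts a [MultiTraitSpec-class]
#' @param spec the [GenomeSpec-class] the scores were simulated from
#' @param seed RNG seed
#' @param popMean per-trait phenotype intercept (population mean;
#'   recycled)
#' @param population population label recorded in the truth (bookkeeping)
#' @return list with `phenotypes` (data.frame: id, then one column per
#'   trait) and `truth` (a [SimTruth-class])
#' @export
simulatePhenotypes <- function(scores, mts, spec, seed = NULL, popMean = 0,
                               population = "pop1") {
    stopifnot(is(mts, "MultiTraitSpec"), is(spec, "GenomeSpec"))
    if (is(scores, "MarkerMatrix")) scores <- genoScores(scores)
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(scores); t <- length(mts@architectures)
    popMean <- rep_len(popMean, t)
    C <- mts@geneticCorr
    sds <- vapply(mts@architectures, function(a) a@polygeneSD, numeric(1))
    npoly <- max(vapply(mts@architectures, function(a) a@nPolygenes, integer(1)))

    G <- matrix(0, n, t)
    qtlRows <- list()
    # shared polygene loci, correlated effects
    if (npoly > 0) {
        polyIdx <- sample.int(ncol(scores), min(npoly, ncol(scores)))
        Sigma <- diag(sds, t) %*% C %*% diag(sds, t)
        ev <- eigen(Sigma, symmetric = TRUE)
        A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), t)
        B <- matrix(rnorm(length(polyIdx) * t), length(polyIdx), t) %*% t(A)
        # per-trait polygene count may be smaller than the shared pool
        for (k in seq_len(t)) {
            nk <- mts@architectures[[k]]@nPolygenes
            if (nk < length(polyIdx)) B[seq_len(length(polyIdx)) > nk, k] <- 0
        }
        Gp <- (scores[, polyIdx, drop = FALSE] - 1) %*% B
        # Recolor the polygenic component in the genetic-value metric so
        # its realized covariance matches the target exactly.  Drawing
        # effects with covariance Sigma is not enough: chromosome-level
        # LD among the carrier markers makes the realized covariance
        # B' C_markers B fluctuate far beyond the target.  The transform
        # acts on trait columns, so the component stays exactly
        # marker-attached (effects become B M).
        sdG <- apply(Gp, 2, sd)
        if (n > t + 1 && min(ev$values) > 1e-10 && all(sdG > 0)) {
            ok <- tryCatch({
                target <- diag(sdG, t) %*% C %*% diag(sdG, t)
                Mx <- solve(chol(cov(Gp))) %*% chol(target)
                B <- B %*% Mx
                Gp <- Gp %*% Mx
                TRUE
            }, error = function(e) FALSE)
        }
        G <- G + Gp
    }
    for (k in seq_len(t)) {
        arch <- mts@architectures[[k]]
        if (arch@nQTLLarge > 0) {
            for (q in seq_len(arch@nQTLLarge)) {
                j <- .nearestMarker(spec, arch@qtlChrom[q], arch@qtlPos[q])
                G[, k] <- G[, k] + arch@qtlEffect[q] * (scores[, j] - 1)
                qtlRows[[length(qtlRows) + 1L]] <- data.frame(
                    trait = mts@traitNames[k], marker = colnames(scores)[j],
                    chrom = arch@qtlChrom[q], posCM = arch@qtlPos[q],
                    effect = arch@qtlEffect[q])
            }
        }
        if (length(arch@presenceLocus)) {
            j <- .nearestMarker(spec, arch@presenceLocus[1], arch@presenceLocus[2])
            off <- scores[, j] == arch@presenceLocus[3]
            G[off, k] <- 0
        }
    }
    Y <- matrix(0, n, t, dimnames = list(rownames(scores), mts@traitNames))
    h2real <- numeric(t)
    for (k in seq_len(t)) {
        h2 <- mts@architectures[[k]]@targetH2
        if (h2 == 0) G[, k] <- 0
        vG <- var(G[, k])
        sdE <- if (h2 >= 1) 0
               else if (vG == 0) max(sds[k], 1)
               else sqrt(vG * (1 - h2) / h2)
        e <- rnorm(n, 0, sdE)
        # calibrate the noise: remove its sample covariance with the
        # genetic values and fix its sample variance, so the realized
        # heritability var(g)/var(y) equals the target exactly
        if (sdE > 0 && sd(e) > 0) {
            if (vG > 0) {
                g <- G[, k]
                e <- e - mean(e) - cov(e, g) / vG * (g - mean(g))
            }
            e <- e * sdE / sd(e)
        }
        Y[, k] <- popMean[k] + G[, k] + e
        vY <- var(Y[, k])
        h2real[k] <- if (vY > 0) vG / vY else 0
    }
    qtl <- if (length(qtlRows)) do.call(rbind, qtlRows)
           else data.frame(trait = character(), marker = character(),
                           chrom = integer(), posCM = numeric(),
                           effect = numeric())
    truth <- new("SimTruth",
                 h2 = matrix(h2real, nrow = 1,
                             dimnames = list(population, mts@traitNames)),
                 qtl = qtl, geneticCorr = C, geneticValues = G)
    phen <- data.frame(id = rownames(scores) %||% sprintf("ind%04d", 1:n), Y,
                       check.names = FALSE)
    list(phenotypes = phen, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Whole-programme simulation
## ---------------------------------------------------------------------------

#' Simulate a multi-cross selfing breeding programme
#'
#' Runs [makeParents], [advanceGenerations] per cross, assembles
#' [MarkerMatrix-class] objects for the F3 and F4 generations of all
#' crosses, and simulates phenotypes via [simulatePhenotypes].  Each
#' cross shares the reference parent; population fixed effects
#' (`popMeans`) default to distinct values per cross so combined-population
#' models have real population means to absorb.
#'
#' @param spec a [GenomeSpec-class]
#' @param mts a [MultiTraitSpec-class]
#' @param scheme a [BreedingScheme-class]
#' @param nCrosses number of biparental crosses sharing parent 1
#' @param seed RNG seed (one master seed; all stages derive from it)
#' @param popMeans matrix (crosses x traits) of population means, or NULL
#'   for defaults 0, 5, -5, ... per cross
#' @param generations which phenotyped generations to build ("F3",
#'   "F4" or both)
#' @param segregatingFraction see [makeParents]
#' @return list with `genotypes` (list of MarkerMatrix, `F3` and `F4`,
#'   populations concatenated), `phenotypes` (data.frame: id, population,
#'   generation, traits), `truth` (per-population [SimTruth-class] list by
#'   generation), `spec`, `trueMap` (data.frame marker/chrom/posCM)
#' @export
simulateBreedingProgram <- function(spec, mts, scheme = breedingScheme(),
                                    nCrosses = 3, seed = 1,
                                    popMeans = NULL,
                                    generations = c("F3", "F4"),
                                    segregatingFraction = 0.7) {
    generations <- match.arg(generations, several.ok = TRUE)
    set.seed(seed)
    t <- length(mts@architectures)
    if (is.null(popMeans)) {
        # modest population mean offsets (about half a within-population
        # phenotypic SD for unit-variance traits), so the n x 3 fixed-effect
        # design has real means to absorb without dominating the phenotype
        base <- c(0, 1, -1, 2, -2)[seq_len(nCrosses)]
        popMeans <- matrix(rep(base, t), nCrosses, t)
    }
    parents <- makeParents(spec, nParents = nCrosses + 1L,
                           segregatingFraction = segregatingFraction)
    popNames <- sprintf("cross%d", seq_len(nCrosses))
    chrom <- .chromIndex(spec)
    posCM <- unlist(spec@markerPos)
    mnames <- .markerNames(spec)
    out <- sapply(generations, function(g) list(), simplify = FALSE)
    phen <- list()
    truth <- sapply(generations, function(g) list(), simplify = FALSE)
    last <- if ("F4" %in% generations) "F4" else "F3"
    for (cx in seq_len(nCrosses)) {
        sim <- advanceGenerations(parents[1, ], parents[cx + 1L, ],
                                  scheme, spec, lastGeneration = last)
        for (gen in generations) {
            sc <- popScores(sim[[gen]])
            colnames(sc) <- mnames
            rownames(sc) <- paste(popNames[cx], sim[[gen]]$ids, sep = "_")
            tg <- as.integer(substring(gen, 2))
            ph <- simulatePhenotypes(sc, mts, spec,
                                     popMean = popMeans[cx, ],
                                     population = popNames[cx])
            out[[gen]][[cx]] <- MarkerMatrix(
                sc, chrom = chrom, posCM = posCM,
                population = rep(popNames[cx], nrow(sc)),
                generation = rep(gen, nrow(sc)),
                line = sim[[gen]]$pedigree$parent)
            phen[[length(phen) + 1L]] <- data.frame(
                id = rownames(sc), population = popNames[cx],
                generation = gen, ph$phenotypes[, -1, drop = FALSE],
                check.names = FALSE)
            truth[[gen]][[popNames[cx]]] <- ph$truth
        }
    }
    genotypes <- lapply(out, function(lst) do.call(SummarizedExperiment::cbind, lst))
    phenotypes <- do.call(rbind, phen)
    rownames(phenotypes) <- NULL
    list(genotypes = genotypes, phenotypes = phenotypes, truth = truth,
         spec = spec,
         trueMap = data.frame(marker = mnames, chrom = chrom, posCM = posCM),
         popMeans = popMeans, seed = seed)
}

#' A perilla-like multi-trait preset
#'
#' Three traits spanning the architectures seen in the programme:
#' an oligogenic presence/absence compound (perillaldehyde-like: two
#' large QTLs plus a locus whose donor homozygote abolishes the trait,
#' h2 = 0.7), a polygenic compound (rosmarinic-acid-like: 300 polygenes,
#' h2 = 0.4), and a high-heritability pigment trait (anthocyanin-like:
#' one major QTL, h2 = 0.8).  Polygenic genetic correlations are mild
#' (-0.15 to 0.3), within the range observed across populations.
#'
#' @param spec a [GenomeSpec-class] (QTL positions are placed on its
#'   first chromosomes)
#' @return a [MultiTraitSpec-class]
#' @export
perillaTraits <- function(spec = perillaGenome()) {
    L <- spec@chromLengths
    # QTL home chromosomes, wrapped into range for small test genomes
    ch <- function(i) (i - 1L) %% spec@nChrom + 1L
    pa <- traitArchitecture(
        qtl = data.frame(chrom = ch(c(5, 7)),
                         posCM = c(0.3 * L[ch(5)], 0.6 * L[ch(7)]),
                         effect = c(1.0, 0.6)),
        nPolygenes = 100, polygeneSD = 0.05, targetH2 = 0.7,
        presenceLocus = c(ch(5), 0.3 * L[ch(5)], 2))
    ra <- traitArchitecture(qtl = NULL, nPolygenes = 300, polygeneSD = 0.1,
                            targetH2 = 0.4)
    ant <- traitArchitecture(
        qtl = data.frame(chrom = ch(8), posCM = 0.5 * L[ch(8)], effect = 1.5),
        nPolygenes = 100, polygeneSD = 0.05, targetH2 = 0.8)
    C <- matrix(c(1, -0.15, 0.3,
                  -0.15, 1, -0.1,
                  0.3, -0.1, 1), 3, 3)
    multiTraitSpec(list(pa, ra, ant), geneticCorr = C,
                   traitNames = c("PA", "RA", "ANT"))
}

#' Write a simulated data set to plain-text files
#'
#' Writes `genotypes_<gen>.csv` (individuals x markers, 0/1/2),
#' `phenotypes.csv` (id, population, generation, traits), `map.csv`
#' (marker, chrom, cM) and `truth.json` (realized heritabilities, QTL
#' assignments, genetic correlation matrix).
#'
#' @param sim output of [simulateBreedingProgram]
#' @param dir output directory (created if needed)
#' @return invisibly, the files written
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (gen in names(sim$genotypes)) {
        f <- file.path(dir, sprintf("genotypes_%s.csv", gen))
        sc <- genoScores(sim$genotypes[[gen]])
        write.csv(data.frame(id = rownames(sc), sc, check.names = FALSE),
                  f, row.names = FALSE)
        files <- c(files, f)
    }
    f <- file.path(dir, "phenotypes.csv")
    write.csv(sim$phenotypes, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "map.csv")
    mapOut <- data.frame(marker = sim$trueMap$marker,
                         chrom = sim$trueMap$chrom, cM = sim$trueMap$posCM)
    write.csv(mapOut, f, row.names = FALSE)
    files <- c(files, f)
    truthList <- lapply(sim$truth, function(byPop)
        lapply(byPop, function(tr) list(
            h2 = as.list(setNames(as.numeric(tr@h2), colnames(tr@h2))),
            qtl = tr@qtl, geneticCorr = tr@geneticCorr)))
    f <- file.path(dir, "truth.json")
    jsonlite::write_json(truthList, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    invisible(files)
}
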