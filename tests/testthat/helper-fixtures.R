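# Shared small fixtures, built in code at test time.

# one biparental cross advanced to F3/F4 on a small genome
smallCrossSim <- function(nChrom = 2, chromLength = 60, markersPerChrom = 7,
                          f2Lines = 60, f2Selected = 40, seedsPerLine = 2,
                          f3Sel = 20, arch = NULL, corr = NULL, seed = 1) {
    spec <- genomeSpec(nChrom, chromLength, markersPerChrom)
    if (is.null(arch))
        arch <- list(traitArchitecture(targetH2 = 0, nPolygenes = 0))
    mts <- multiTraitSpec(arch, geneticCorr = corr)
    sim <- simulateBreedingProgram(
        spec, mts, breedingScheme(f2Lines, f2Selected, seedsPerLine,
                                  f3Sel, f3Sel),
        nCrosses = 1, seed = seed)
    sim$mts <- mts
    sim
}

# a pair of F3 marker columns at a given true (Haldane) map distance
f3MarkerPair <- function(dCM, n = 300, seed = 1) {
    spec <- genomeSpec(1, max(dCM, 1e-6) + 1e-6, markerPos = list(c(0, dCM)))
    mts <- multiTraitSpec(list(traitArchitecture(targetH2 = 0,
                                                 nPolygenes = 0)))
    lines <- ceiling(n / 3)
    sim <- simulateBreedingProgram(
        spec, mts,
        breedingScheme(lines + 10, lines, 3,
                       ceiling(lines / 2), floor(lines / 2)),
        nCrosses = 1, seed = seed)
    genoScores(sim$genotypes$F3)[seq_len(n), ]
}

# HWE-like random-mating genotype panel (for GRM diagonal properties)
hwePanel <- function(n, m, seed = 1, pmin = 0.1, pmax = 0.9) {
    set.seed(seed)
    p <- runif(m, pmin, pmax)
    W <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
    colnames(W) <- sprintf("M%04d", seq_len(m))
    W
}
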