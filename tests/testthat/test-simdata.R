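# Breeding-scheme simulator: parents, meiosis, generation advance,
# phenotypes with known truth.

test_that("parents are fully inbred and the cross pair segregates everywhere", {
    spec <- genomeSpec(2, 50, 5)
    par <- makeParents(spec, nParents = 2, seed = 1)
    expect_true(all(par %in% c(0L, 1L)))
    # scores of an inbred parent are twice its haplotype: only 0 or 2
    expect_true(all((2 * par) %in% c(0, 2)))
    expect_true(all(par[1, ] == 0))
    expect_true(all(par[2, ] == 1))     # designated pair differs at all markers
    # extra parents differ at a subset
    par4 <- makeParents(spec, nParents = 4, seed = 1,
                        segregatingFraction = 0.5)
    expect_equal(mean(par4[3, ] != par4[1, ]), 0.5)
    # determinism
    expect_identical(makeParents(spec, 3, seed = 9),
                     makeParents(spec, 3, seed = 9))
})

test_that("meiosis respects the no-recombination and unlinked limits", {
    # vanishingly short chromosome: gamete equals one parental haplotype
    spec0 <- genomeSpec(1, 1e-9, markerPos = list(c(0, 5e-10, 1e-9)))
    h1 <- c(0L, 0L, 0L); h2 <- c(1L, 1L, 1L)
    set.seed(3)
    gams <- replicate(400, meiosis(h1, h2, spec0))
    sums <- colSums(gams)
    expect_true(all(sums %in% c(0, 3)))            # never a recombinant
    expect_gt(mean(sums == 0), 0.4)                # both parents drawn ~1/2
    expect_lt(mean(sums == 0), 0.6)
    expect_error(meiosis(c(0L, 1L), h2, spec0), "length")
})

test_that("meiosis recombinant fraction follows the Haldane map function", {
    spec <- genomeSpec(1, 10, markerPos = list(c(0, 10)))
    set.seed(11)
    gams <- replicate(20000, meiosis(c(0L, 0L), c(1L, 1L), spec))
    recFrac <- mean(gams[1, ] != gams[2, ])
    expect_equal(recFrac, 0.5 * (1 - exp(-0.2)), tolerance = 0.035)
    # unlinked limit at very long distance
    specL <- genomeSpec(1, 1000, markerPos = list(c(0, 1000)))
    set.seed(12)
    gamsL <- replicate(4000, meiosis(c(0L, 0L), c(1L, 1L), specL))
    expect_equal(mean(gamsL[1, ] != gamsL[2, ]), 0.5, tolerance = 0.03)
})

test_that("generation advance reproduces the selfing class frequencies", {
    # 100 unlinked loci (one marker per chromosome) and one seed per
    # line, so the 100 x 100 genotype draws are mutually independent and
    # the multinomial goodness-of-fit test applies
    spec <- genomeSpec(100, 60, 1)
    par <- makeParents(spec, 2, seed = 2)
    set.seed(13)
    gens <- advanceGenerations(par[1, ], par[2, ],
                               breedingScheme(120, 100, 1, 50, 50),
                               spec, seed = 13)
    # F1 heterozygous everywhere
    expect_true(all(popScores(gens$F1) == 1))
    # F2 1:2:1 over many loci
    f2 <- popScores(gens$F2)
    tab2 <- table(factor(f2, levels = 0:2)) / length(f2)
    expect_lt(max(abs(tab2 - c(1, 2, 1) / 4)), 0.02)
    # F3 3:2:3 (random selection)
    f3 <- popScores(gens$F3)
    tab3 <- table(factor(f3, levels = 0:2)) / length(f3)
    chi <- sum((table(factor(f3, levels = 0:2)) -
                length(f3) * c(3, 2, 3) / 8)^2 /
               (length(f3) * c(3, 2, 3) / 8))
    expect_gt(stats::pchisq(chi, df = 2, lower.tail = FALSE), 0.001)
    # F4 heterozygote fraction 1/8 (selfing halves heterozygosity)
    f4 <- popScores(gens$F4)
    expect_lt(abs(mean(f4 == 1) - 1 / 8), 0.012)
    # pedigree wiring: every F4 individual has a selected F3 parent
    expect_true(all(gens$F4$pedigree$parent %in% gens$F3$ids))
    expect_identical(nrow(f4), 100L)
})

test_that("scheme validation rejects impossible counts", {
    expect_error(breedingScheme(f2Lines = 50, f2Selected = 100), "<=")
    expect_error(breedingScheme(f2Selected = 10, seedsPerLine = 1,
                                f3SelectedGrown = 20, f3SelectedUngrown = 20),
                 "exceed")
})

test_that("truncation selection shifts the selected-line mean upward", {
    spec <- genomeSpec(1, 60, 10)
    arch <- traitArchitecture(qtl = data.frame(chrom = 1, posCM = 30,
                                               effect = 1),
                              targetH2 = 1)
    par <- makeParents(spec, 2)
    gRand <- advanceGenerations(par[1, ], par[2, ],
                                breedingScheme(80, 20, 2, 10, 10),
                                spec, seed = 5)
    gTrunc <- advanceGenerations(par[1, ], par[2, ],
                                 breedingScheme(80, 20, 2, 10, 10,
                                                selectionMode = "truncation"),
                                 spec, seed = 5, truncationTrait = arch)
    qtlScore <- function(g) mean(popScores(g$F4))
    expect_gt(qtlScore(gTrunc), qtlScore(gRand))
    expect_error(advanceGenerations(par[1, ], par[2, ],
        breedingScheme(selectionMode = "truncation"), spec), "truncationTrait")
})

test_that("phenotype simulation calibrates heritability and applies the presence rule", {
    spec <- genomeSpec(3, 80, 20)
    sim <- smallCrossSim(nChrom = 3, markersPerChrom = 20,
                         f2Lines = 120, f2Selected = 100, seedsPerLine = 3,
                         f3Sel = 50, seed = 17)
    sc <- genoScores(sim$genotypes$F3)
    arch <- traitArchitecture(qtl = data.frame(chrom = 1, posCM = 40,
                                               effect = 1),
                              nPolygenes = 30, polygeneSD = 0.1,
                              targetH2 = 0.6)
    ph <- simulatePhenotypes(sc, multiTraitSpec(list(arch)), sim$spec,
                             seed = 3)
    expect_lt(abs(unname(ph$truth@h2[1, 1]) - 0.6), 0.02)

    # degenerate heritabilities
    ph0 <- simulatePhenotypes(sc, multiTraitSpec(list(
        traitArchitecture(qtl = data.frame(chrom = 1, posCM = 40, effect = 1),
                          targetH2 = 0))), sim$spec, seed = 4)
    expect_true(all(ph0$truth@geneticValues == 0))
    ph1 <- simulatePhenotypes(sc, multiTraitSpec(list(
        traitArchitecture(qtl = data.frame(chrom = 1, posCM = 40, effect = 1),
                          targetH2 = 1))), sim$spec, seed = 5, popMean = 2)
    expect_equal(ph1$phenotypes[, 2], 2 + ph1$truth@geneticValues[, 1],
                 tolerance = 1e-12, ignore_attr = TRUE)

    # presence/absence: abolishing homozygotes have genetic value 0
    archPA <- traitArchitecture(qtl = data.frame(chrom = 1, posCM = 40,
                                                 effect = 1),
                                targetH2 = 0.8,
                                presenceLocus = c(2, 40, 2))
    phPA <- simulatePhenotypes(sc, multiTraitSpec(list(archPA)), sim$spec,
                               seed = 6)
    j <- selfGP:::.nearestMarker(sim$spec, 2, 40)
    off <- sc[, j] == 2
    expect_true(any(off))
    expect_true(all(phPA$truth@geneticValues[off, 1] == 0))
    expect_true(any(phPA$truth@geneticValues[!off, 1] != 0))
})

test_that("multi-trait genetic values realize the requested correlation", {
    spec <- genomeSpec(4, 70, 30)
    mts <- multiTraitSpec(
        list(traitArchitecture(nPolygenes = 120, polygeneSD = 0.1,
                               targetH2 = 0.6),
             traitArchitecture(nPolygenes = 120, polygeneSD = 0.1,
                               targetH2 = 0.6)),
        geneticCorr = matrix(c(1, 0.6, 0.6, 1), 2))
    sim <- simulateBreedingProgram(spec, mts,
                                   breedingScheme(250, 220, 3, 110, 110),
                                   nCrosses = 1, seed = 23)
    tr <- sim$truth$F3$cross1
    g <- tr@geneticValues
    expect_gt(nrow(g), 600)
    expect_lt(abs(cor(g[, 1], g[, 2]) - 0.6), 0.08)
    expect_error(multiTraitSpec(list(traitArchitecture(), traitArchitecture()),
                                geneticCorr = matrix(c(1, 2, 2, 1), 2)))
})

test_that("simulation is reproducible and seed-sensitive", {
    s1 <- smallCrossSim(seed = 101)
    s2 <- smallCrossSim(seed = 101)
    s3 <- smallCrossSim(seed = 102)
    expect_identical(genoScores(s1$genotypes$F4), genoScores(s2$genotypes$F4))
    expect_identical(s1$phenotypes, s2$phenotypes)
    expect_false(identical(genoScores(s1$genotypes$F4),
                           genoScores(s3$genotypes$F4)))
})

test_that("written simulation files round-trip", {
    sim <- smallCrossSim(seed = 41)
    d <- tempfile()
    files <- writeSimulation(sim, d)
    expect_true(all(file.exists(file.path(d, c("genotypes_F3.csv",
        "genotypes_F4.csv", "phenotypes.csv", "map.csv", "truth.json")))))
    mm <- readGenotypes(file.path(d, "genotypes_F3.csv"), format = "csv",
                        mapPath = file.path(d, "map.csv"))
    expect_true(all(genoScores(mm) == genoScores(sim$genotypes$F3)))
    truth <- jsonlite::read_json(file.path(d, "truth.json"))
    expect_named(truth, c("F3", "F4"))
})
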