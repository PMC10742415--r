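# Scan grids, cofactor selection, CIM regression, permutation thresholds.

# one-population F3 fixture with a known map from the simulated truth
scanFixture <- function(arch, seed, nChrom = 3, markersPerChrom = 8,
                        f2 = 110, sel = 100) {
    spec <- genomeSpec(nChrom, 60, markersPerChrom)
    mts <- multiTraitSpec(arch)
    sim <- simulateBreedingProgram(spec, mts,
                                   breedingScheme(f2, sel, 3, 50, 50),
                                   nCrosses = 1, seed = seed)
    mm <- sim$genotypes$F3
    list(mm = mm, map = mapFromMarkerInfo(mm), sim = sim,
         y = sim$phenotypes$trait1[sim$phenotypes$generation == "F3"])
}

test_that("conditional probabilities: observed markers, marginals, enumeration", {
    fx <- scanFixture(list(traitArchitecture(targetH2 = 0, nPolygenes = 0)),
                      seed = 201, nChrom = 1, markersPerChrom = 4)
    sc <- genoScores(fx$mm)
    # introduce missingness at both flanks for one individual
    sc[3, ] <- NA
    mm <- MarkerMatrix(sc, chrom = markerInfo(fx$mm)$chrom,
                       posCM = markerInfo(fx$mm)$posCM,
                       population = populations(fx$mm))
    grid <- conditionalProbs(mm, fx$map, t = 3, step = 1)
    pos <- grid@positions
    # at a marker position, probability mass 1 on the observed class
    mk <- mapTable(fx$map)
    j <- which(abs(pos$cM - mk$cM[2]) < 1e-9)[1]
    probs <- cbind(grid@p0[, j], grid@p1[, j], grid@p2[, j])
    obs <- sc[, mk$marker[2]]
    for (i in which(!is.na(obs)))
        expect_equal(unname(probs[i, obs[i] + 1]), 1, tolerance = 1e-9)
    # individual missing everywhere gets the F3 marginal 3:2:3
    expect_equal(unname(probs[3, ]), c(3, 2, 3) / 8, tolerance = 1e-12)
    # rows always sum to 1
    expect_lt(max(abs(grid@p0 + grid@p1 + grid@p2 - 1)), 1e-9)
})

test_that("midpoint conditionals match the three-locus enumeration oracle", {
    # flanks 10 cM apart, both scored 0; the midpoint class-0 probability
    # from the exact three-locus F3 distribution
    r <- kosambiInv(5)
    arr <- oracleClassJoint(c(r, r), 3)           # 3 x 3 x 3 classes
    want <- arr[1, , 1] / sum(arr[1, , 1])        # P(mid | left=0, right=0)
    J <- jointTable(selfingJoint(r, 3))
    marg <- c(3, 2, 3) / 8
    got <- J[1, ] * J[, 1] / marg
    got <- got / sum(got)
    expect_gt(got[1], 0.9)
    expect_lt(max(abs(got - want)), 0.01)
})

test_that("cofactor selection is greedy, deterministic, and finds planted signal", {
    fx <- scanFixture(list(traitArchitecture(targetH2 = 0, nPolygenes = 0)),
                      seed = 205)
    sc <- genoScores(fx$mm)
    # noise-free phenotype equal to one marker's scores: chosen first
    y <- sc[, 13]
    expect_identical(selectCofactors(fx$mm, y, k = 3)[1], colnames(sc)[13])
    expect_identical(selectCofactors(fx$mm, y, k = 0), character())
    expect_identical(selectCofactors(fx$mm, y, k = 3),
                     selectCofactors(fx$mm, y, k = 3))
    expect_error(selectCofactors(fx$mm, y, k = length(y)), "k")
})

test_that("cofactors recover the markers nearest two large QTLs", {
    hits <- vapply(1:10, function(s) {
        fx <- scanFixture(list(traitArchitecture(
            qtl = data.frame(chrom = c(1, 2), posCM = c(20, 45),
                             effect = c(1, 1)),
            nPolygenes = 0, polygeneSD = 0, targetH2 = 0.6)),
            seed = 500 + s)
        qtl <- unique(fx$sim$truth$F3$cross1@qtl$marker)
        chosen <- selectCofactors(fx$mm, fx$y, k = 5)
        all(qtl %in% chosen)
    }, logical(1))
    expect_gte(mean(hits), 0.8)
})

test_that("CIM at a marker equals the single-marker regression oracle", {
    fx <- scanFixture(list(traitArchitecture(
        qtl = data.frame(chrom = 1, posCM = 30, effect = 0.8),
        nPolygenes = 0, polygeneSD = 0, targetH2 = 0.4)),
        seed = 207, nChrom = 1, markersPerChrom = 2)
    grid <- conditionalProbs(fx$mm, fx$map, t = 3, step = 1)
    scan <- cimScan(grid, fx$y, fx$mm, fx$map, cofactors = character())
    tab <- scanTable(scan)
    mk <- mapTable(fx$map)
    sc <- genoScores(fx$mm)
    for (i in 1:2) {
        j <- which(abs(tab$cM - mk$cM[i]) < 1e-9)[1]
        want <- oracleMarkerLOD(fx$y, sc[, mk$marker[i]])
        expect_equal(tab$lod[j], want, tolerance = 1e-8)
    }
})

test_that("LOD is invariant to affine transformation of the phenotype", {
    fx <- scanFixture(list(traitArchitecture(
        qtl = data.frame(chrom = 2, posCM = 30, effect = 1),
        nPolygenes = 0, polygeneSD = 0, targetH2 = 0.3)),
        seed = 208)
    grid <- conditionalProbs(fx$mm, fx$map, t = 3, step = 2)
    cof <- selectCofactors(fx$mm, fx$y, k = 3)
    s1 <- scanTable(cimScan(grid, fx$y, fx$mm, fx$map, cof))
    s2 <- scanTable(cimScan(grid, 3 - 2.5 * fx$y, fx$mm, fx$map, cof))
    expect_lt(max(abs(s1$lod - s2$lod)), 1e-7)
})

test_that("null phenotypes give small LODs; perfect fits are capped", {
    fx <- scanFixture(list(traitArchitecture(targetH2 = 0, nPolygenes = 0)),
                      seed = 209)
    grid <- conditionalProbs(fx$mm, fx$map, t = 3, step = 2)
    scan <- cimScan(grid, fx$y, fx$mm, fx$map)
    expect_lt(max(scanTable(scan)$lod), 4)
    # phenotype exactly equal to an additive marker dosage: capped + flagged
    sc <- genoScores(fx$mm)
    scanP <- cimScan(grid, sc[, 5], fx$mm, fx$map)
    tabP <- scanTable(scanP)
    mk <- markerInfo(fx$mm)[5, ]
    j <- which(tabP$chrom == mk$chrom &
               abs(tabP$cM - mapTable(fx$map)$cM[5]) < 1e-6)
    expect_equal(tabP$lod[j], 50)
    expect_true(tabP$degenerate[j])
})

test_that("widening the window only removes cofactors and keeps LOD >= 0", {
    fx <- scanFixture(list(traitArchitecture(
        qtl = data.frame(chrom = 1, posCM = 30, effect = 1),
        nPolygenes = 0, polygeneSD = 0, targetH2 = 0.5)),
        seed = 210)
    grid <- conditionalProbs(fx$mm, fx$map, t = 3, step = 2)
    cof <- selectCofactors(fx$mm, fx$y, k = 5)
    for (w in c(5, 15, 40)) {
        tab <- scanTable(cimScan(grid, fx$y, fx$mm, fx$map, cof,
                                 windowCM = w))
        expect_true(all(tab$lod >= 0))
    }
})

test_that("permutation thresholds are seeded, monotone in alpha, and sane", {
    fx <- scanFixture(list(traitArchitecture(targetH2 = 0, nPolygenes = 0)),
                      seed = 211)
    grid <- conditionalProbs(fx$mm, fx$map, t = 3, step = 2)
    cof <- selectCofactors(fx$mm, fx$y, k = 3)
    p1 <- permutationThreshold(grid, fx$y, fx$mm, fx$map, cof,
                               nPerm = 120, alpha = 0.05, seed = 5)
    p2 <- permutationThreshold(grid, fx$y, fx$mm, fx$map, cof,
                               nPerm = 120, alpha = 0.05, seed = 5)
    expect_identical(p1$threshold, p2$threshold)
    expect_gt(p1$threshold, 0)
    # alpha = 1 gives the minimum of the permutation maxima
    pAll <- permutationThreshold(grid, fx$y, fx$mm, fx$map, cof,
                                 nPerm = 120, alpha = 1, seed = 5)
    expect_equal(pAll$threshold, min(pAll$maxLod))
    expect_error(permutationThreshold(grid, fx$y, fx$mm, fx$map, cof,
                                      nPerm = 50), ">= 100")
})

test_that("qtlScan localizes a 20%-variance QTL and reports peak segments", {
    fx <- scanFixture(list(traitArchitecture(
        qtl = data.frame(chrom = 2, posCM = 30, effect = 1),
        nPolygenes = 0, polygeneSD = 0, targetH2 = 0.2)),
        seed = 212)
    scan <- qtlScan(fx$mm, fx$map, fx$y, t = 3, step = 2, k = 5,
                    nPerm = 120, seed = 6)
    pk <- scanPeaks(scan)
    expect_gt(nrow(pk), 0)
    top <- pk[which.max(pk$lod), ]
    qtlMarker <- fx$sim$truth$F3$cross1@qtl$marker[1]
    mk <- mapTable(fx$map)
    truePos <- mk$cM[mk$marker == qtlMarker]
    expect_identical(as.character(top$chrom),
                     as.character(mk$chrom[mk$marker == qtlMarker]))
    expect_lt(abs(top$cM - truePos), 10)
})
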