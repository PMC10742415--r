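# F_t selfing segregation model, recombination ML, map functions and
# linkage-map construction.

test_that("selfing joint matches exhaustive gamete-pair enumeration", {
    for (t in 2:4) {
        for (r in seq(0, 0.5, by = 0.1)) {
            got <- jointTable(selfingJoint(r, t))
            want <- oracleClassJoint(r, t)
            expect_lt(max(abs(got - want)), 1e-12)
        }
    }
})

test_that("selfing joint degenerate cases and marginals", {
    # complete linkage: diagonal with the F3 3:2:3 classes
    j0 <- jointTable(selfingJoint(0, 3))
    expect_equal(diag(j0), c(3, 2, 3) / 8, ignore_attr = TRUE)
    expect_equal(sum(abs(j0)) - sum(diag(j0)), 0)
    # free recombination: product of independent 3:2:3 marginals
    j5 <- jointTable(selfingJoint(0.5, 3))
    expect_equal(unname(j5), outer(c(3, 2, 3) / 8, c(3, 2, 3) / 8),
                 tolerance = 1e-12)
    # single-locus marginal is exactly 3:2:3 at t = 3 for every r
    for (r in seq(0, 0.5, by = 0.05)) {
        tab <- jointTable(selfingJoint(r, 3))
        expect_equal(unname(rowSums(tab)), c(3, 2, 3) / 8, tolerance = 1e-12)
        expect_equal(unname(colSums(tab)), c(3, 2, 3) / 8, tolerance = 1e-12)
        # symmetry under simultaneous swap of hom classes at both loci
        expect_equal(tab, tab[3:1, 3:1], ignore_attr = TRUE)
    }
    # heterozygote fraction halves per generation
    expect_equal(unname(selfingMarginal(4)[2]), 1 / 8)
    expect_equal(unname(selfingMarginal(2)), c(1, 2, 1) / 4)
    expect_error(selfingJoint(0.6, 3), "0.5")
    expect_error(selfingJoint(0.2, 1), ">= 2")
})

test_that("recombination ML: degenerate and boundary behaviour", {
    # perfect cosegregation
    a <- c(0, 0, 1, 2, 2, 1, 0, 2, 1, 0)
    est <- estimateRecombination(a, a, 3)
    expect_equal(rHat(est), 0, tolerance = 1e-8)
    expect_identical(est@nInformative, 10L)
    # statistically independent loci push r_hat to the 0.5 boundary
    set.seed(42)
    marg <- c(3, 2, 3) / 8
    highs <- replicate(20, {
        x <- sample(0:2, 300, TRUE, prob = marg)
        y <- sample(0:2, 300, TRUE, prob = marg)
        rHat(estimateRecombination(x, y, 3))
    })
    expect_gte(mean(highs > 0.4), 0.8)
    # missing values drop individuals from the informative count
    b <- a; b[1:3] <- NA
    expect_identical(estimateRecombination(a, b, 3)@nInformative, 7L)
    expect_error(estimateRecombination(c(0, NA), c(NA, 1), 3), "informative")
})

test_that("recombination ML recovers simulated F3 fractions", {
    # true r = 0.1 corresponds to a Haldane distance of ~11.16 cM
    d <- haldane(0.1)
    errs <- vapply(1:25, function(s) {
        sc <- f3MarkerPair(d, n = 300, seed = 1000 + s)
        abs(rHat(estimateRecombination(sc[, 1], sc[, 2], 3)) - 0.1)
    }, numeric(1))
    expect_gte(mean(errs <= 0.05), 0.95)
})

test_that("recombination ML is invariant to parent coding at one locus", {
    sc <- f3MarkerPair(haldane(0.15), n = 200, seed = 7)
    e1 <- rHat(estimateRecombination(sc[, 1], sc[, 2], 3))
    e2 <- rHat(estimateRecombination(sc[, 1], 2 - sc[, 2], 3))
    e3 <- rHat(estimateRecombination(2 - sc[, 1], sc[, 2], 3))
    expect_equal(e1, e2, tolerance = 1e-9)
    expect_equal(e1, e3, tolerance = 1e-9)
})

test_that("Kosambi and Haldane map functions", {
    expect_equal(kosambi(0), 0)
    expect_equal(kosambi(0.25), 25 * log(3))
    # round trip on a dense grid
    r <- seq(0, 0.49, by = 0.005)
    expect_lt(max(abs(kosambiInv(kosambi(r)) - r)), 1e-10)
    d <- seq(0, 200, by = 2.5)
    expect_lt(max(abs(kosambi(kosambiInv(d)) - d)), 1e-10)
    expect_error(kosambi(0.5))
    expect_error(kosambiInv(-1))
    expect_equal(haldaneInv(haldane(0.3)), 0.3, tolerance = 1e-12)
})

test_that("buildMap recovers an equidistant map and drops bad markers", {
    spec <- genomeSpec(1, 50, 11)  # 11 markers, 5 cM true spacing
    mts <- multiTraitSpec(list(traitArchitecture(targetH2 = 0,
                                                 nPolygenes = 0)))
    sim <- simulateBreedingProgram(spec, mts,
                                   breedingScheme(110, 100, 3, 50, 50),
                                   nCrosses = 1, seed = 21)
    mm <- sim$genotypes$F3
    map <- buildMap(mm, t = 3)
    tab <- mapTable(map)
    expect_identical(nrow(tab), 11L)
    expect_equal(tab$cM[1], 0)
    gaps <- diff(tab$cM)
    expect_true(all(gaps >= 2 & gaps <= 9))
    expect_gt(sum(gaps), 0.7 * 50)
    expect_lt(sum(gaps), 1.3 * 50)

    # a phase-inconsistent (miscoded) marker looks like repulsion to the
    # coupling chain model: its adjacent r_hat hits the 0.5 boundary and
    # it is dropped and logged
    sc <- genoScores(mm)
    sc[, 6] <- 2 - sc[, 6]
    mm2 <- MarkerMatrix(sc, chrom = markerInfo(mm)$chrom,
                        posCM = markerInfo(mm)$posCM,
                        population = populations(mm))
    map2 <- suppressMessages(buildMap(mm2, t = 3))
    expect_true(colnames(sc)[6] %in% droppedMarkers(map2))
    expect_identical(nrow(mapTable(map2)), 10L)

    # duplicated marker: zero gap, both retained
    sc3 <- cbind(sc[, 1, drop = FALSE], sc)
    colnames(sc3)[1] <- "dup"
    mm3 <- MarkerMatrix(sc3, chrom = c(1, markerInfo(mm)$chrom),
                        posCM = c(0, markerInfo(mm)$posCM),
                        population = populations(mm))
    map3 <- suppressMessages(buildMap(mm3, t = 3))
    tab3 <- mapTable(map3)
    expect_true(all(c("dup", colnames(sc)[1]) %in% tab3$marker))
    expect_equal(tab3$cM[2] - tab3$cM[1], 0, tolerance = 1e-8)
})

test_that("map length is monotone as markers are appended", {
    sim <- smallCrossSim(nChrom = 1, markersPerChrom = 8, seed = 31)
    mm <- sim$genotypes$F3
    lens <- vapply(3:8, function(k) {
        sub <- mm[seq_len(k), ]
        sum(mapLength(buildMap(sub, t = 3)))
    }, numeric(1))
    expect_true(all(diff(lens) >= -1e-9))
})

test_that("consensus map: passthrough, coincident maps, affine rescalings", {
    mkmap <- function(cm, chrom = "1") {
        new("LinkageMap",
            positions = data.frame(marker = sprintf("m%02d", seq_along(cm)),
                                   chrom = chrom, cM = cm),
            dropped = character(), generation = 3L)
    }
    truth <- c(0, 5, 12, 20, 26, 33, 41, 50, 55, 63)
    # three identical maps -> consensus equals the common map
    cons <- consensusMap(list(mkmap(truth), mkmap(truth), mkmap(truth)),
                         span = 0.75)
    expect_lt(max(abs(mapTable(cons)$cM - truth)), 1e-6)
    # single map: smoothed, monotone, same span
    one <- consensusMap(list(mkmap(truth)), span = 0.75)
    expect_true(all(diff(mapTable(one)$cM) >= 0))
    expect_equal(mapTable(one)$cM[1], 0)
    # affine rescalings of one truth: consensus within 10% everywhere
    maps <- list(mkmap(truth * 0.8), mkmap(truth), mkmap(truth * 1.2))
    cons2 <- consensusMap(maps, span = 0.75)
    got <- mapTable(cons2)$cM
    expect_lt(max(abs(got[-1] - truth[-1]) / truth[-1]), 0.10)
})

test_that("consensus map handles population-specific marker subsets", {
    truth <- seq(0, 45, by = 5)
    mk <- function(keep) {
        cm <- truth[keep] - truth[keep][1]
        new("LinkageMap",
            positions = data.frame(marker = sprintf("m%02d", which(keep)),
                                   chrom = "1", cM = cm),
            dropped = character(), generation = 3L)
    }
    keepA <- rep(TRUE, 10); keepB <- rep(TRUE, 10); keepB[c(3, 7)] <- FALSE
    cons <- consensusMap(list(mk(keepA), mk(keepB)), span = 0.8)
    tab <- mapTable(cons)
    expect_identical(nrow(tab), 10L)  # union of markers
    expect_true(all(diff(tab$cM) >= 0))
})
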