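## Cross-validated prediction accuracy and pipeline orchestration.

#' Seeded cross-validation fold assignments
#'
#' Random partition of the individuals into `nFolds` folds per repeat,
#' with fold sizes differing by at most one (within each stratum when
#' stratified).  A stratum smaller than `nFolds` falls back to plain
#' random assignment for that stratum, with a warning.
#'
#' @param ids individual ids (or an integer count)
#' @param nFolds folds per repeat (>= 2)
#' @param nRepeats number of repeats
#' @param seed RNG seed
#' @param strata optional stratification labels (e.g. population), one
#'   per individual
#' @return list of length `nRepeats`; each element an integer fold
#'   assignment (1..nFolds) named by id
#' @export
makeFolds <- function(ids, nFolds = 10, nRepeats = 10, seed = 1,
                      strata = NULL) {
    if (length(ids) == 1L && is.numeric(ids)) ids <- as.character(seq_len(ids))
    n <- length(ids)
    stopifnot(nFolds >= 2, n >= nFolds)
    set.seed(seed)
    out <- vector("list", nRepeats)
    for (r in seq_len(nRepeats)) {
        fold <- integer(n)
        if (is.null(strata)) {
            fold <- sample(rep_len(seq_len(nFolds), n))
        } else {
            for (s in unique(strata)) {
                idx <- which(strata == s)
                if (length(idx) < nFolds)
                    warning("stratum '", s, "' smaller than nFolds; ",
                            "assigning it unstratified")
                fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
            }
        }
        names(fold) <- ids
        out[[r]] <- fold
    }
    out
}

#' Cross-validated genomic prediction accuracy
#'
#' Repeated k-fold cross-validation of a genomic prediction model.  Per
#' repeat, each fold is held out in turn, the model is trained on the
#' rest and the held-out individuals are predicted; all held-out
#' predictions of the repeat are pooled and a single Pearson correlation
#' with the observed values is computed.  The accuracy is the mean of
#' the per-repeat correlations (set `perFoldCorrelation = TRUE` for the
#' alternative per-fold-then-average reading).  For GBLUP the
#' relationship matrix is computed once over all individuals (standard
#' practice; relatedness, not phenotypes, crosses the fold boundary).
#'
#' @param y complete phenotype vector
#' @param model "gblup" or "bayesb"
#' @param G relationship matrix or [GRM-class] over all individuals
#'   (gblup)
#' @param W marker score matrix (bayesb)
#' @param population optional population labels; when given, GBLUP uses
#'   population-mean fixed effects and folds are stratified by
#'   population
#' @param nFolds,nRepeats cross-validation scheme (default 10 x 10)
#' @param seed RNG seed (folds and chains)
#' @param perFoldCorrelation compute Pearson r per fold and average,
#'   instead of pooling the repeat's held-out predictions
#' @param chain list of chain settings for bayesb (nIter, burnIn)
#' @return a [CVResult-class]
#' @export
crossValidate <- function(y, model = c("gblup", "bayesb"), G = NULL,
                          W = NULL, population = NULL, nFolds = 10,
                          nRepeats = 10, seed = 1,
                          perFoldCorrelation = FALSE,
                          chain = list(nIter = 1500, burnIn = 500)) {
    model <- match.arg(model)
    if (anyNA(y)) stop("phenotype must be complete")
    n <- length(y)
    if (model == "gblup") {
        if (is.null(G)) stop("gblup needs G")
        if (is(G, "GRM")) G <- relMatrix(G)
        stopifnot(nrow(G) == n)
    } else {
        if (is.null(W)) stop("bayesb needs W")
        W <- as.matrix(W)
        stopifnot(nrow(W) == n)
    }
    X <- if (!is.null(population)) {
        f <- as.factor(population)
        mm <- stats::model.matrix(~ 0 + f)
        colnames(mm) <- levels(f)
        mm
    } else matrix(1, n, 1)
    folds <- makeFolds(n, nFolds, nRepeats, seed = seed, strata = population)
    perRepeat <- numeric(0)
    rows <- list()
    for (r in seq_len(nRepeats)) {
        pred <- rep(NA_real_, n)
        for (f in seq_len(nFolds)) {
            test <- folds[[r]] == f
            if (model == "gblup") {
                ytr <- y; ytr[test] <- NA
                fit <- fitGBLUP(ytr, G, X = X)
                pred[test] <- predict(fit)[test]
            } else {
                fit <- fitBayesB(y[!test], W[!test, , drop = FALSE],
                                 X = X[!test, , drop = FALSE],
                                 nIter = chain$nIter, burnIn = chain$burnIn,
                                 seed = seed + 7919L * r + f)
                pred[test] <- predictMarkers(fit, W[test, , drop = FALSE],
                                             X = X[test, , drop = FALSE])
            }
            rf <- if (sd(y[test]) > 0 && sd(pred[test]) > 0)
                cor(y[test], pred[test]) else NA_real_
            rows[[length(rows) + 1L]] <- data.frame(
                rep = r, fold = f, r = rf, n = sum(test))
        }
        rr <- if (perFoldCorrelation) {
            rs <- vapply(rows[(length(rows) - nFolds + 1):length(rows)],
                         function(d) d$r, numeric(1))
            mean(rs, na.rm = TRUE)
        } else if (sd(y) > 0 && sd(pred) > 0) {
            cor(y, pred)
        } else NA_real_
        if (is.na(rr))
            warning("repeat ", r, ": correlation undefined; excluded")
        else perRepeat <- c(perRepeat, rr)
    }
    perFold <- do.call(rbind, rows)
    new("CVResult", perRepeat = perRepeat,
        accuracy = mean(perRepeat), sd = sd(perRepeat),
        perFold = perFold,
        scheme = list(nFolds = nFolds, nRepeats = nRepeats, seed = seed,
                      stratified = !is.null(population), model = model,
                      pooled = !perFoldCorrelation))
}

## ---------------------------------------------------------------------------
## Pipeline
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' A complete demo configuration: three simulated crosses advanced to
#' F3/F4 with the perilla-like genome and trait preset, MAF filtering,
#' per-population and consensus maps, a composite-interval-mapping scan
#' of the first trait, single- and multi-trait heritability and genetic
#' correlations per population and combined, and cross-validated
#' accuracy for GBLUP and BayesB.  Override any element via the `...`
#' of [runPipeline] or by editing the returned list.
#'
#' @return a named list
#' @export
defaultPipelineConfig <- function() {
    list(
        seed = 1,
        nCrosses = 3,
        genome = list(nChrom = 20, chromLength = 70, markersPerChrom = 30),
        traits = "perilla",
        scheme = list(),
        generation = "F3",
        stages = c("simulate", "filter", "map", "scan", "fit", "cv"),
        maf = 0.025,
        scan = list(trait = "PA", step = 2, k = 5, window = 10,
                    nPerm = 200, alpha = 0.05),
        cv = list(trait = "PA", models = c("gblup", "bayesb"),
                  nFolds = 5, nRepeats = 2,
                  chain = list(nIter = 1500, burnIn = 500)),
        outDir = NULL)
}

.knownStages <- c("simulate", "filter", "map", "scan", "fit", "cv")

#' Run the full analysis pipeline
#'
#' Executes simulate -> filter -> map -> scan -> fit -> cv as configured
#' and returns (and optionally writes) the report bundle: a per-trait
#' heritability table (per population and combined), genetic-correlation
#' matrices, QTL scan tables with permutation thresholds and peaks, and
#' a cross-validated accuracy table.  Every output carries the master
#' seed and a hash of the configuration; reruns with the same
#' configuration are bit-identical.
#'
#' Stage names are validated and stage dependencies checked (e.g. a scan
#' without a map) before anything is executed.
#'
#' @param config configuration list as from [defaultPipelineConfig];
#'   elements supplied via `...` override it
#' @param ... overrides merged into `config`
#' @return invisibly, a list with elements `heritability`,
#'   `geneticCorrelations`, `scans`, `peaks`, `cv`, `maps`, `sim`,
#'   `configHash`, `seeds`
#' @export
runPipeline <- function(config = defaultPipelineConfig(), ...) {
    config <- modifyList(config, list(...))
    bad <- setdiff(config$stages, .knownStages)
    if (length(bad))
        stop("unknown stage name(s): ", paste(bad, collapse = ", "))
    st <- config$stages
    need <- function(stage, deps) {
        miss <- setdiff(deps, st)
        if (stage %in% st && length(miss))
            stop("stage '", stage, "' requires stage(s): ",
                 paste(miss, collapse = ", "))
    }
    need("filter", "simulate"); need("map", c("simulate", "filter"))
    need("scan", c("simulate", "filter", "map"))
    need("fit", c("simulate", "filter")); need("cv", c("simulate", "filter"))

    cfgFile <- tempfile(fileext = ".txt")
    writeLines(deparse(config[setdiff(names(config), "outDir")]), cfgFile)
    configHash <- unname(tools::md5sum(cfgFile))
    unlink(cfgFile)
    seeds <- local({ set.seed(config$seed); sample.int(1e6, 8) })

    out <- list(configHash = configHash, seeds = seeds, config = config)

    ## simulate ---------------------------------------------------------
    spec <- genomeSpec(config$genome$nChrom,
                       config$genome$chromLength %||% config$genome$chromLengths,
                       markersPerChrom = config$genome$markersPerChrom,
                       markerPos = config$genome$markerPos)
    mts <- if (identical(config$traits, "perilla")) perillaTraits(spec)
           else config$traits
    scheme <- do.call(breedingScheme, config$scheme)
    sim <- simulateBreedingProgram(spec, mts, scheme,
                                   nCrosses = config$nCrosses,
                                   seed = seeds[1])
    out$sim <- sim
    gen <- config$generation
    t <- as.integer(substring(gen, 2))
    mm <- sim$genotypes[[gen]]

    ## filter -----------------------------------------------------------
    if ("filter" %in% st) {
        fl <- mafFilter(mm, threshold = config$maf, byPopulation = TRUE)
        mm <- imputeMissing(fl$matrix)
        out$filterReport <- fl$report
    }
    pops <- unique(populations(mm))
    perPopMM <- lapply(pops, function(p) {
        sub <- mm[, populations(mm) == p]
        if ("filter" %in% st)
            sub <- sub[intersect(markerIds(sub),
                                 out$filterReport@perPopulation[[p]]), ]
        sub
    })
    names(perPopMM) <- pops
    phen <- sim$phenotypes[sim$phenotypes$generation == gen, ]
    stopifnot(identical(phen$id, individualIds(mm)))
    traitNames <- mts@traitNames

    ## map --------------------------------------------------------------
    if ("map" %in% st) {
        # maps are always estimated from the F3 generation (the protocol's
        # choice) and reused for later generations
        mmF3 <- sim$genotypes$F3
        popMaps <- lapply(pops, function(p) {
            sub <- mmF3[markerIds(perPopMM[[p]]), populations(mmF3) == p]
            buildMap(sub, t = 3)
        })
        names(popMaps) <- pops
        cons <- consensusMap(popMaps)
        out$maps <- list(perPopulation = popMaps, consensus = cons)
    }

    ## scan -------------------------------------------------------------
    if ("scan" %in% st) {
        sc <- config$scan
        scans <- list()
        for (p in pops) {
            yp <- phen[[sc$trait]][phen$population == p]
            scans[[p]] <- qtlScan(perPopMM[[p]], out$maps$consensus, yp,
                                  t = t, step = sc$step, k = sc$k,
                                  windowCM = sc$window, nPerm = sc$nPerm,
                                  alpha = sc$alpha, seed = seeds[2])
        }
        out$scans <- scans
        out$peaks <- do.call(rbind, lapply(names(scans), function(p) {
            pk <- scanPeaks(scans[[p]])
            if (nrow(pk)) cbind(population = p, trait = sc$trait, pk)
            else NULL
        }))
    }

    ## fit --------------------------------------------------------------
    if ("fit" %in% st) {
        h2rows <- list()
        corrs <- list()
        grms <- lapply(perPopMM, computeGRM, normalization = "observed")
        grmAll <- computeGRM(mm, normalization = "observed")
        for (tr in traitNames) {
            for (p in pops) {
                yp <- phen[[tr]][phen$population == p]
                fit <- fitGBLUP(yp, grms[[p]])
                h2rows[[length(h2rows) + 1L]] <- data.frame(
                    trait = tr, population = p, h2 = heritability(fit))
            }
            fitAll <- fitGBLUPMultipop(phen[[tr]], phen$population, grmAll)
            h2rows[[length(h2rows) + 1L]] <- data.frame(
                trait = tr, population = "combined", h2 = heritability(fitAll))
        }
        Y <- as.matrix(phen[, traitNames, drop = FALSE])
        for (p in pops) {
            mt <- fitMultitraitGBLUP(Y[phen$population == p, , drop = FALSE],
                                     grms[[p]])
            corrs[[p]] <- geneticCorrelations(mt)
        }
        Xpop <- stats::model.matrix(~ 0 + factor(phen$population))
        mtAll <- fitMultitraitGBLUP(Y, grmAll, X = Xpop)
        corrs[["combined"]] <- geneticCorrelations(mtAll)
        out$heritability <- do.call(rbind, h2rows)
        out$geneticCorrelations <- corrs
        out$grm <- grmAll
    }

    ## cv ---------------------------------------------------------------
    if ("cv" %in% st) {
        cvc <- config$cv
        yall <- phen[[cvc$trait]]
        Wall <- genoScores(mm)
        rows <- list()
        for (mdl in cvc$models) {
            res <- crossValidate(yall, model = mdl,
                                 G = if (mdl == "gblup") out$grm %||% computeGRM(mm, normalization = "observed"),
                                 W = if (mdl == "bayesb") Wall,
                                 population = phen$population,
                                 nFolds = cvc$nFolds, nRepeats = cvc$nRepeats,
                                 seed = seeds[3], chain = cvc$chain)
            rows[[mdl]] <- data.frame(trait = cvc$trait, model = mdl,
                                      population = "combined",
                                      accuracy = accuracy(res),
                                      sd = res@sd)
        }
        out$cv <- do.call(rbind, rows)
    }

    if (!is.null(config$outDir)) .writePipeline(out, config$outDir)
    invisible(out)
}

.writePipeline <- function(out, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(x, f) if (!is.null(x))
        write.csv(x, file.path(dir, f), row.names = FALSE)
    wcsv(out$heritability, "heritability.csv")
    wcsv(out$cv, "cv_accuracy.csv")
    wcsv(out$peaks, "qtl_peaks.csv")
    if (!is.null(out$scans))
        for (p in names(out$scans))
            wcsv(scanTable(out$scans[[p]]), sprintf("scan_%s.csv", p))
    if (!is.null(out$maps))
        wcsv(mapTable(out$maps$consensus), "consensus_map.csv")
    if (!is.null(out$geneticCorrelations)) {
        long <- do.call(rbind, lapply(names(out$geneticCorrelations),
            function(p) {
                C <- out$geneticCorrelations[[p]]
                data.frame(population = p,
                           trait1 = rep(rownames(C), ncol(C)),
                           trait2 = rep(colnames(C), each = nrow(C)),
                           rG = as.numeric(C))
            }))
        wcsv(long, "genetic_correlations.csv")
    }
    info <- list(configHash = out$configHash, seed = out$config$seed,
                 stageSeeds = out$seeds)
    jsonlite::write_json(info, file.path(dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(out$scans)) {
        thr <- lapply(out$scans, function(s)
            list(alpha = s@alpha, nPerm = s@nPerm, value = s@threshold))
        jsonlite::write_json(thr, file.path(dir, "thresholds.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}
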