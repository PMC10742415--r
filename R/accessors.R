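## Accessors and show methods.  Slot access from user code should go
## through these, not `@`.

#' @rdname MarkerMatrix
#' @param mm a MarkerMatrix
#' @return `genoScores()`: numeric matrix of scores, individuals x markers.
#' @export
genoScores <- function(mm) t(assay(mm, "score"))

#' @rdname MarkerMatrix
#' @return `markerInfo()`: data.frame of marker metadata (chrom, posCM, posBp).
#' @export
markerInfo <- function(mm) as.data.frame(rowData(mm))

#' @rdname MarkerMatrix
#' @return `populations()`: character vector of population labels per individual.
#' @export
populations <- function(mm) as.character(colData(mm)$population)

#' @rdname MarkerMatrix
#' @export
nMarkers <- function(mm) nrow(mm)

#' @rdname MarkerMatrix
#' @export
nIndividuals <- function(mm) ncol(mm)

#' @rdname MarkerMatrix
#' @export
markerIds <- function(mm) rownames(mm)

#' @rdname MarkerMatrix
#' @export
individualIds <- function(mm) colnames(mm)

#' Subset a MarkerMatrix by marker ids and/or individual ids
#'
#' @param mm a MarkerMatrix
#' @param markers marker ids (or logical/integer index) to keep
#' @param individuals individual ids (or logical/integer index) to keep
#' @return the subset MarkerMatrix
#' @export
subsetMarkers <- function(mm, markers = NULL, individuals = NULL) {
    if (!is.null(markers)) mm <- mm[markers, ]
    if (!is.null(individuals)) mm <- mm[, individuals]
    mm
}

setMethod("show", "MarkerMatrix", function(object) {
    pops <- table(populations(object))
    cat("MarkerMatrix:", nMarkers(object), "markers x",
        nIndividuals(object), "individuals\n")
    cat("  populations:",
        paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
        "\n")
    sc <- assay(object, "score")
    cat(sprintf("  missing scores: %d (%.2f%%)\n", sum(is.na(sc)),
                100 * mean(is.na(sc))))
    cat("  chromosomes:", length(unique(markerInfo(object)$chrom)), "\n")
})

#' @rdname SelfingJoint-class
#' @param x a SelfingJoint
#' @return `jointTable()`: the 3x3 joint probability matrix.
#' @export
jointTable <- function(x) x@table

setMethod("show", "SelfingJoint", function(object) {
    cat(sprintf("SelfingJoint: F%d, r = %.4f\n", object@t, object@r))
    print(round(object@table, 5))
})

#' @rdname RecombEstimate-class
#' @param x a RecombEstimate
#' @export
rHat <- function(x) x@rHat

setMethod("show", "RecombEstimate", function(object) {
    cat(sprintf("RecombEstimate: r_hat = %.4f (logLik = %.3f, n = %d)\n",
                object@rHat, object@logLik, object@nInformative))
})

#' @rdname LinkageMap-class
#' @param map a LinkageMap
#' @return `mapTable()`: data.frame with marker, chrom, cM.
#' @export
mapTable <- function(map) map@positions

#' @rdname LinkageMap-class
#' @return `mapLength()`: named vector of chromosome lengths in cM.
#' @export
mapLength <- function(map) {
    pos <- map@positions
    vapply(split(pos$cM, pos$chrom), function(x) max(x) - min(x), numeric(1))
}

#' @rdname LinkageMap-class
#' @return `droppedMarkers()`: ids of markers dropped during construction.
#' @export
droppedMarkers <- function(map) map@dropped

setMethod("show", "LinkageMap", function(object) {
    pos <- object@positions
    cat(sprintf("LinkageMap: %d markers on %d chromosomes, total %.1f cM\n",
                nrow(pos), length(unique(pos$chrom)), sum(mapLength(object))))
    if (length(object@dropped))
        cat("  dropped markers:", length(object@dropped), "\n")
})

#' @rdname QTLScanResult-class
#' @param x a QTLScanResult
#' @return `scanTable()`: data.frame with chrom, cM, lod.
#' @export
scanTable <- function(x) x@table

#' @rdname QTLScanResult-class
#' @return `lodThreshold()`: the genome-wide permutation LOD threshold.
#' @export
lodThreshold <- function(x) x@threshold

#' Above-threshold peaks of a QTL scan
#'
#' Contiguous runs of grid positions with LOD at or above the genome-wide
#' threshold are merged into segments (per chromosome); each segment is
#' reported once, at the position of its maximum LOD.  This is the
#' counting convention used throughout: one peak per contiguous
#' above-threshold segment, not one per grid position.
#'
#' @param x a QTLScanResult with a threshold set
#' @return data.frame with chrom, cM (peak position), lod, segStartCM, segEndCM
#' @export
scanPeaks <- function(x) {
    stopifnot(is(x, "QTLScanResult"))
    if (is.na(x@threshold))
        stop("no threshold set; run permutationThreshold() first")
    tab <- x@table
    out <- list()
    for (ch in unique(tab$chrom)) {
        sub <- tab[tab$chrom == ch, ]
        sub <- sub[order(sub$cM), ]
        above <- sub$lod >= x@threshold
        if (!any(above)) next
        runs <- rle(above)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        for (k in which(runs$values)) {
            seg <- sub[starts[k]:ends[k], ]
            top <- seg[which.max(seg$lod), ]
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch, cM = top$cM, lod = top$lod,
                segStartCM = min(seg$cM), segEndCM = max(seg$cM))
        }
    }
    if (!length(out))
        return(data.frame(chrom = character(), cM = numeric(), lod = numeric(),
                          segStartCM = numeric(), segEndCM = numeric()))
    do.call(rbind, out)
}

setMethod("show", "QTLScanResult", function(object) {
    cat(sprintf("QTLScanResult: %d positions, max LOD %.2f\n",
                nrow(object@table), max(object@table$lod)))
    cat("  cofactors:", length(object@cofactors),
        " window:", object@windowCM, "cM\n")
    if (!is.na(object@threshold))
        cat(sprintf("  threshold (alpha = %.3g, %d perms): %.3f; peaks: %d\n",
                    object@alpha, object@nPerm, object@threshold,
                    nrow(scanPeaks(object))))
})

#' @rdname GRM-class
#' @param x a GRM
#' @return `relMatrix()`: the g x g relationship matrix.
#' @export
relMatrix <- function(x) x@G

setMethod("show", "GRM", function(object) {
    cat(sprintf("GRM: %d x %d, mean diagonal %.3f, norm constant %.3f\n",
                nrow(object@G), ncol(object@G), mean(diag(object@G)),
                object@normConstant))
    if (length(object@excluded))
        cat("  monomorphic markers excluded:", length(object@excluded), "\n")
})

#' Genomic heritability of a fitted model
#'
#' @param fit a GPFit or MultiTraitFit
#' @return single-trait: scalar h2; multi-trait: per-trait vector
#'   K_ii / (K_ii + R_ii).
#' @export
setGeneric("heritability", function(fit) standardGeneric("heritability"))

#' @rdname heritability
setMethod("heritability", "GPFit", function(fit) fit@h2)

#' @rdname heritability
setMethod("heritability", "MultiTraitFit", function(fit) fit@h2)

#' Variance components of a fitted GBLUP model
#'
#' @param fit a GPFit
#' @return named vector c(sigma2u, sigma2e)
#' @export
varComponents <- function(fit) {
    stopifnot(is(fit, "GPFit"))
    c(sigma2u = fit@sigma2u, sigma2e = fit@sigma2e)
}

#' @rdname GPFit-class
#' @param fit a GPFit
#' @export
geneticValues <- function(fit) {
    stopifnot(is(fit, "GPFit"))
    fit@u
}

#' @rdname GPFit-class
#' @export
fixedEffects <- function(fit) {
    stopifnot(is(fit, "GPFit"))
    fit@beta
}

setMethod("show", "GPFit", function(object) {
    cat(sprintf("GPFit (%s): sigma2u = %.4g, sigma2e = %.4g, h2 = %.3f\n",
                object@model, object@sigma2u, object@sigma2e, object@h2))
})

#' Genetic correlation matrix of a multi-trait fit
#'
#' @param fit a MultiTraitFit
#' @return t x t genetic correlation matrix
#' @export
geneticCorrelations <- function(fit) {
    stopifnot(is(fit, "MultiTraitFit"))
    fit@geneticCorr
}

setMethod("show", "MultiTraitFit", function(object) {
    t <- nrow(object@K)
    cat(sprintf("MultiTraitFit: %d traits, h2 = %s%s\n", t,
                paste(sprintf("%.3f", object@h2), collapse = ", "),
                if (object@converged) "" else " (EM not converged)"))
    cat("genetic correlations:\n")
    print(round(object@geneticCorr, 3))
})

#' @rdname MarkerEffectFit-class
#' @param x a MarkerEffectFit
#' @return `markerEffects()`: posterior mean effects (m x t).
#' @export
markerEffects <- function(x) x@effects

#' @rdname MarkerEffectFit-class
#' @return `inclusionProb()`: posterior inclusion probability per marker.
#' @export
inclusionProb <- function(x) x@inclusionProb

setMethod("show", "MarkerEffectFit", function(object) {
    cat(sprintf("MarkerEffectFit (%s): %d markers, pi_hat = %.3f\n",
                object@model, nrow(object@effects), object@pi))
    cat(sprintf("  chain: %d iterations, %d burn-in\n",
                object@chain$nIter, object@chain$burnIn))
})

#' @rdname CVResult-class
#' @param x a CVResult
#' @return `accuracy()`: mean over repeats of the per-repeat Pearson
#'   correlations between observed and predicted held-out values.
#' @export
accuracy <- function(x) {
    stopifnot(is(x, "CVResult"))
    x@accuracy
}

#' @rdname CVResult-class
#' @export
repeatCorrelations <- function(x) {
    stopifnot(is(x, "CVResult"))
    x@perRepeat
}

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: accuracy = %.3f (sd %.3f over %d repeats)\n",
                object@accuracy, object@sd, length(object@perRepeat)))
})
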