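## Reading, validating, filtering and encoding marker data.
##
## Genotypes are coded 0/1/2 relative to a reference parent (0 =
## homozygous for the reference parent, 1 = heterozygous, 2 = homozygous
## for the other parent), the coding used throughout the analysis.

#' Read genotypes into a MarkerMatrix
#'
#' `format = "csv"` expects a table with an `id` column followed by one
#' 0/1/2 column per marker, plus a map file (`marker`, `chrom`, `cM`
#' columns; optionally `bp`) giving marker coordinates.  `format = "vcf"`
#' reads biallelic SNPs and recodes GT fields to 0/1/2: when
#' `referenceParent` names a sample, scores count alleles different from
#' that parent's (homozygous) allele; otherwise the REF allele is taken
#' as the reference-parent allele and the score is the ALT dosage.
#' Missing GT (`./.`) becomes a missing score.  Markers are ordered
#' chromosome-then-position.  Multiallelic sites are rejected with their
#' ids.
#'
#' @param path genotype file (CSV or VCF; VCF may be bgzipped)
#' @param format "csv" or "vcf"
#' @param mapPath map CSV (required for csv format)
#' @param referenceParent sample id of the reference parent (vcf format)
#' @param populations population label per individual: a single label, a
#'   vector named by individual id, or NULL for "pop1"
#' @return a [MarkerMatrix-class]
#' @export
readGenotypes <- function(path, format = c("csv", "vcf"), mapPath = NULL,
                          referenceParent = NULL, populations = NULL) {
    format <- match.arg(format)
    if (format == "csv") {
        if (is.null(mapPath)) stop("csv format needs a mapPath")
        geno <- read.csv(path, check.names = FALSE)
        map <- read.csv(mapPath)
        ids <- as.character(geno[[1]])
        sc <- as.matrix(geno[, -1, drop = FALSE])
        rownames(sc) <- ids
        common <- intersect(colnames(sc), map$marker)
        if (!length(common)) stop("no markers shared between genotype and map files")
        map <- map[match(common, map$marker), ]
        ord <- order(map$chrom, map$cM)
        map <- map[ord, ]
        sc <- sc[, map$marker, drop = FALSE]
        pop <- .popLabels(populations, ids)
        return(MarkerMatrix(sc, chrom = map$chrom, posCM = map$cM,
                            posBp = if ("bp" %in% names(map)) map$bp else NA_integer_,
                            population = pop))
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
        stop("multiallelic sites are not supported: ",
             paste(head(fix[multi, "ID"], 10), collapse = ", "))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- colnames(gt)
    dosage <- function(g) {
        # ALT-allele dosage; NA for missing
        out <- rep(NA_real_, length(g))
        g <- gsub("|", "/", g, fixed = TRUE)
        known <- !is.na(g) & g %in% c("0/0", "0/1", "1/0", "1/1")
        out[g %in% "0/0"] <- 0
        out[g %in% c("0/1", "1/0")] <- 1
        out[g %in% "1/1"] <- 2
        out[!known] <- NA_real_
        out
    }
    sc <- apply(gt, 2, dosage)
    rownames(sc) <- rownames(gt)
    if (!is.null(referenceParent)) {
        if (!referenceParent %in% ids)
            stop("unknown reference parent: ", referenceParent)
        ref <- sc[, referenceParent]
        if (any(ref == 1, na.rm = TRUE))
            stop("reference parent is heterozygous at ",
                 sum(ref == 1, na.rm = TRUE), " site(s); it must be inbred")
        # where the parent carries the ALT allele, flip the dosage so the
        # parent's genotype scores 0
        flip <- !is.na(ref) & ref == 2
        sc[flip, ] <- 2 - sc[flip, ]
    }
    nmiss <- sum(is.na(sc))
    if (nmiss > 0)
        message("readGenotypes: ", nmiss, " missing genotype call(s)")
    chrom <- fix[, "CHROM"]
    pos <- as.numeric(fix[, "POS"])
    ord <- order(chrom, pos)
    sc <- t(sc[ord, , drop = FALSE])
    pop <- .popLabels(populations, ids)
    mm <- MarkerMatrix(sc, chrom = chrom[ord], posCM = rep(NA_real_, ncol(sc)),
                       posBp = pos[ord], population = pop)
    validObject(mm)
    mm
}

.popLabels <- function(populations, ids) {
    if (is.null(populations)) return(rep("pop1", length(ids)))
    if (length(populations) == 1L && is.null(names(populations)))
        return(rep(populations, length(ids)))
    if (!is.null(names(populations))) {
        if (!all(ids %in% names(populations)))
            stop("populations vector is missing labels for some individuals")
        return(as.character(populations[ids]))
    }
    if (length(populations) != length(ids))
        stop("populations must be length 1 or one label per individual")
    as.character(populations)
}

#' Write a MarkerMatrix as a biallelic VCF
#'
#' GT fields encode the 0/1/2 scores (0 = homozygous reference-parent
#' allele, written as the REF allele).  Physical positions come from the
#' `posBp` metadata when present, otherwise from the cM position on a
#' configurable physical scale.
#'
#' @param mm a [MarkerMatrix-class]
#' @param path output path (written gzip-compressed, `.vcf.gz`)
#' @param bpPerCM physical scale used when no `posBp` is available
#' @return invisibly, `path`
#' @export
writeGenotypesVCF <- function(mm, path, bpPerCM = 1e5) {
    info <- markerInfo(mm)
    posBp <- info$posBp
    if (is.null(posBp) || all(is.na(posBp)))
        posBp <- as.integer(round(info$posCM * bpPerCM)) + 1L
    fix <- cbind(CHROM = as.character(info$chrom),
                 POS = as.character(posBp),
                 ID = markerIds(mm), REF = "A", ALT = "T",
                 QUAL = ".", FILTER = "PASS", INFO = ".")
    sc <- assay(mm, "score")
    gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(sc), ncol(sc), dimnames = dimnames(sc))
    for (v in names(gtcode)) gt[!is.na(sc) & sc == as.numeric(v)] <- gtcode[[v]]
    gt <- cbind(FORMAT = "GT", gt)
    meta <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    obj <- new("vcfR", meta = meta, fix = fix, gt = gt)
    vcfR::write.vcf(obj, file = path)
    invisible(path)
}

#' Allele frequencies and MAF of each marker
#'
#' The frequency of the non-reference allele is computed as
#' sum(scores) / (2 * non-missing count); the MAF is the smaller of the
#' two allele frequencies.
#'
#' @param mm a [MarkerMatrix-class]
#' @return data.frame with `marker`, `freq` (non-reference allele) and
#'   `maf`
#' @export
alleleFreq <- function(mm) {
    sc <- assay(mm, "score")
    n2 <- 2 * rowSums(!is.na(sc))
    p <- rowSums(sc, na.rm = TRUE) / n2
    data.frame(marker = markerIds(mm), freq = p, maf = pmin(p, 1 - p),
               row.names = NULL)
}

#' Filter markers on minor allele frequency
#'
#' A marker is removed when its MAF is strictly below `threshold` in the
#' evaluated scope (a MAF exactly at the threshold is retained).  With
#' `byPopulation = TRUE` the MAF is evaluated within each population
#' label separately; each population's retained marker set is reported
#' (populations generally retain different counts), and the returned
#' matrix keeps the union of the per-population sets.
#'
#' @param mm a [MarkerMatrix-class]
#' @param threshold MAF threshold in [0, 0.5]
#' @param byPopulation evaluate per population label?
#' @return list with `matrix` (the filtered [MarkerMatrix-class]) and
#'   `report` (a [FilterReport-class]; per-population retained ids in its
#'   `perPopulation` slot when `byPopulation`)
#' @export
mafFilter <- function(mm, threshold = 0.025, byPopulation = FALSE) {
    stopifnot(threshold >= 0, threshold <= 0.5)
    mIn <- nMarkers(mm)
    perPop <- list()
    if (byPopulation) {
        for (p in unique(populations(mm))) {
            sub <- mm[, populations(mm) == p]
            af <- alleleFreq(sub)
            perPop[[p]] <- af$marker[af$maf >= threshold]
        }
        keepIds <- unique(unlist(perPop))
        keep <- markerIds(mm) %in% keepIds
    } else {
        af <- alleleFreq(mm)
        keep <- af$maf >= threshold
    }
    if (!any(keep))
        stop("all markers removed by MAF filter at threshold ", threshold)
    out <- mm[keep, ]
    report <- new("FilterReport", markersIn = mIn,
                  markersRemoved = as.integer(mIn - sum(keep)),
                  markersOut = as.integer(sum(keep)),
                  threshold = threshold, byPopulation = byPopulation,
                  perPopulation = perPop)
    list(matrix = out, report = report)
}

setMethod("show", "FilterReport", function(object) {
    cat(sprintf("FilterReport: %d in, %d removed (MAF < %g), %d out%s\n",
                object@markersIn, object@markersRemoved, object@threshold,
                object@markersOut,
                if (object@byPopulation) " [per population]" else ""))
    for (p in names(object@perPopulation))
        cat(sprintf("  %s: %d markers retained\n", p,
                    length(object@perPopulation[[p]])))
})

#' Modal imputation of missing genotype scores
#'
#' Missing scores are replaced by the per-marker, per-population modal
#' score; ties are broken toward the lower score.  This deliberately
#' simple rule (not LD-aware) is adequate for the low missingness rates
#' the rest of the pipeline assumes; markers missing in more than 90%
#' of a population's individuals are refused, as is a marker entirely
#' missing within a population.
#'
#' @param mm a [MarkerMatrix-class]
#' @return a complete [MarkerMatrix-class]; the number of imputed cells
#'   is recorded in `metadata(mm)$imputed`
#' @export
imputeMissing <- function(mm) {
    sc <- assay(mm, "score")
    pops <- populations(mm)
    nImp <- 0L
    for (p in unique(pops)) {
        cols <- which(pops == p)
        sub <- sc[, cols, drop = FALSE]
        missFrac <- rowMeans(is.na(sub))
        if (any(missFrac > 0.9))
            stop("markers missing in >90% of population ", p, ": ",
                 paste(head(rownames(sub)[missFrac > 0.9], 5), collapse = ", "))
        for (j in which(missFrac > 0)) {
            x <- sub[j, ]
            tab <- table(factor(x, levels = 0:2))
            mode <- as.numeric(names(tab)[which.max(tab)])  # ties -> lower
            nImp <- nImp + sum(is.na(x))
            sub[j, is.na(x)] <- mode
        }
        sc[, cols] <- sub
    }
    if (nImp > 0) message("imputeMissing: imputed ", nImp, " score(s)")
    out <- mm
    SummarizedExperiment::assay(out, "score") <- sc
    metadata(out)$imputed <- nImp
    out
}
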