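#' @import methods
#' @importFrom stats var cor sd quantile optimize loess predict isoreg
#'   rnorm rpois runif rbinom complete.cases setNames aggregate coef lm
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom vcfR vcfR
#' @useDynLib selfGP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## MarkerMatrix: biallelic SNP scores for one or more breeding populations.
##
## Stored as a SummarizedExperiment with markers as rows and individuals as
## columns (the Bioconductor features-by-samples convention).  The single
## assay "score" holds 0/1/2 genotype scores relative to a designated
## reference parent: 0 = homozygous for the reference parent, 1 =
## heterozygous, 2 = homozygous for the other parent; NA = missing call.
## ---------------------------------------------------------------------------

#' MarkerMatrix: genotype scores with marker and individual metadata
#'
#' A container for biallelic SNP genotype scores of one or more biparental
#' breeding populations, stored as a [SummarizedExperiment::SummarizedExperiment]
#' with markers as rows and individuals as columns.  Scores are coded
#' relative to a reference parent: 0 = homozygous reference parent,
#' 1 = heterozygous, 2 = homozygous other parent, `NA` = missing.
#'
#' Row metadata carries `chrom` (linkage group) and `posCM` (map position,
#' centiMorgans, chromosome-local origin 0) and optionally `posBp`
#' (1-based physical position).  Column metadata carries `population`
#' (cross label) and optionally `generation` and `line` (pedigree).
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment]
#' @export
setClass("MarkerMatrix", contains = "SummarizedExperiment")

setValidity("MarkerMatrix", function(object) {
    msg <- character()
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'score' is required")
    else {
        sc <- assay(object, "score")
        ok <- is.na(sc) | sc %in% c(0, 1, 2)
        if (!all(ok))
            msg <- c(msg, "scores must be 0, 1, 2 or NA")
    }
    if (!all(c("chrom", "posCM") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain 'chrom' and 'posCM'")
    if (!"population" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'population'")
    if (length(msg)) msg else TRUE
})

#' Construct a MarkerMatrix
#'
#' @param scores numeric matrix of 0/1/2 scores, individuals in rows and
#'   markers in columns (the orientation used by the downstream models);
#'   it is transposed into the markers-by-individuals assay.
#' @param chrom chromosome / linkage-group label per marker.
#' @param posCM map position in centiMorgans per marker (origin 0 per
#'   chromosome).
#' @param population population (cross) label per individual.
#' @param posBp optional 1-based physical position per marker.
#' @param generation optional generation label per individual (e.g. "F3").
#' @param line optional pedigree line identifier per individual.
#'
#' @return A [MarkerMatrix-class] object.
#' @export
MarkerMatrix <- function(scores, chrom, posCM, population,
                         posBp = NA_integer_, generation = NA_character_,
                         line = NA_character_) {
    scores <- as.matrix(scores)
    if (is.null(colnames(scores)))
        colnames(scores) <- sprintf("M%04d", seq_len(ncol(scores)))
    if (is.null(rownames(scores)))
        rownames(scores) <- sprintf("ind%04d", seq_len(nrow(scores)))
    rd <- DataFrame(chrom = as.character(chrom), posCM = as.numeric(posCM),
                    posBp = posBp, row.names = colnames(scores))
    cd <- DataFrame(population = as.character(population),
                    generation = generation, line = line,
                    row.names = rownames(scores))
    se <- SummarizedExperiment(assays = list(score = t(scores)),
                               rowData = rd, colData = cd)
    new("MarkerMatrix", se)
}

## ---------------------------------------------------------------------------
## Remaining value classes (plain S4)
## ---------------------------------------------------------------------------

#' Genome specification for the breeding-scheme simulator
#'
#' @slot nChrom number of chromosomes (linkage groups)
#' @slot chromLengths length of each chromosome in centiMorgans
#' @slot markerPos list (one numeric vector per chromosome) of marker
#'   positions in cM, strictly increasing within a chromosome
#' @export
setClass("GenomeSpec",
         representation(nChrom = "integer", chromLengths = "numeric",
                        markerPos = "list"))

setValidity("GenomeSpec", function(object) {
    msg <- character()
    if (object@nChrom < 1L) msg <- c(msg, "nChrom must be >= 1")
    if (length(object@chromLengths) != object@nChrom)
        msg <- c(msg, "chromLengths length must equal nChrom")
    if (any(object@chromLengths <= 0))
        msg <- c(msg, "chromosome lengths must be > 0")
    if (length(object@markerPos) != object@nChrom)
        msg <- c(msg, "markerPos must have one vector per chromosome")
    for (i in seq_along(object@markerPos)) {
        p <- object@markerPos[[i]]
        if (length(p) && any(diff(p) <= 0)) {
            msg <- c(msg, sprintf(
                "marker positions on chromosome %d must be strictly increasing", i))
        }
        if (length(p) && (min(p) < 0 || max(p) > object@chromLengths[i]))
            msg <- c(msg, sprintf(
                "marker positions on chromosome %d must lie within [0, length]", i))
    }
    if (length(msg)) msg else TRUE
})

#' Breeding scheme parameters
#'
#' Defaults follow the selection scheme of a typical three-cross
#' selfing programme: 200 F2 lines per cross, 100 selected and selfed with
#' three seeds per line to give the F3, 100 F3 lines selected (half from
#' those grown in the field, half from those not grown) and selfed with
#' three seeds per line to give the F4.
#'
#' @slot f2Lines F2 lines grown per cross
#' @slot f2Selected F2 lines selected for selfing
#' @slot seedsPerLine offspring per selected line in the next generation
#' @slot f3SelectedGrown F3 lines selected among those grown in the field
#' @slot f3SelectedUngrown F3 lines selected among those not grown
#' @slot selectionMode "random" or "truncation" (truncation on a trait)
#' @export
setClass("BreedingScheme",
         representation(f2Lines = "integer", f2Selected = "integer",
                        seedsPerLine = "integer", f3SelectedGrown = "integer",
                        f3SelectedUngrown = "integer", selectionMode = "character"))

setValidity("BreedingScheme", function(object) {
    msg <- character()
    cnt <- c(object@f2Lines, object@f2Selected, object@seedsPerLine,
             object@f3SelectedGrown, object@f3SelectedUngrown)
    if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
    if (object@f2Selected > object@f2Lines)
        msg <- c(msg, "f2Selected must be <= f2Lines")
    nF3 <- object@f2Selected * object@seedsPerLine
    if (object@f3SelectedGrown + object@f3SelectedUngrown > nF3)
        msg <- c(msg, "F3 selections exceed the number of F3 individuals")
    if (!object@selectionMode %in% c("random", "truncation"))
        msg <- c(msg, "selectionMode must be 'random' or 'truncation'")
    if (length(msg)) msg else TRUE
})

#' Trait architecture for the phenotype simulator
#'
#' @slot nQTLLarge number of large-effect QTLs
#' @slot qtlChrom,qtlPos,qtlEffect per-QTL chromosome, cM position and
#'   additive effect (trait units per allele substitution)
#' @slot nPolygenes number of small-effect polygenic loci
#' @slot polygeneSD standard deviation of polygene additive effects
#' @slot targetH2 target narrow-sense genomic heritability in [0, 1]
#' @slot presenceLocus optional length-3 numeric (chrom, cM, abolishing
#'   homozygous score 0 or 2): individuals homozygous for that parent at
#'   the locus get genetic value 0 before noise (presence/absence trait)
#' @export
setClass("TraitArchitecture",
         representation(nQTLLarge = "integer", qtlChrom = "integer",
                        qtlPos = "numeric", qtlEffect = "numeric",
                        nPolygenes = "integer", polygeneSD = "numeric",
                        targetH2 = "numeric", presenceLocus = "numeric"))

setValidity("TraitArchitecture", function(object) {
    msg <- character()
    if (object@targetH2 < 0 || object@targetH2 > 1)
        msg <- c(msg, "targetH2 must lie in [0, 1]")
    if (length(object@qtlPos) != object@nQTLLarge ||
        length(object@qtlChrom) != object@nQTLLarge ||
        length(object@qtlEffect) != object@nQTLLarge)
        msg <- c(msg, "QTL chrom/pos/effect must each have nQTLLarge entries")
    if (length(object@presenceLocus) &&
        !(length(object@presenceLocus) == 3 &&
          object@presenceLocus[3] %in% c(0, 2)))
        msg <- c(msg, "presenceLocus must be c(chrom, cM, score) with score 0 or 2")
    if (length(msg)) msg else TRUE
})

#' Multi-trait architecture: several traits with correlated polygenes
#'
#' @slot architectures list of [TraitArchitecture-class], one per trait
#' @slot geneticCorr t-by-t genetic correlation matrix for the shared
#'   polygenic effects (symmetric, unit diagonal, positive semidefinite)
#' @slot traitNames trait labels
#' @export
setClass("MultiTraitSpec",
         representation(architectures = "list", geneticCorr = "matrix",
                        traitNames = "character"))

setValidity("MultiTraitSpec", function(object) {
    msg <- character()
    t <- length(object@architectures)
    C <- object@geneticCorr
    if (!all(dim(C) == c(t, t)))
        msg <- c(msg, "geneticCorr must be t x t")
    else {
        if (max(abs(C - t(C))) > 1e-8) msg <- c(msg, "geneticCorr must be symmetric")
        if (max(abs(diag(C) - 1)) > 1e-8) msg <- c(msg, "geneticCorr must have unit diagonal")
        ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8) msg <- c(msg, "geneticCorr must be positive semidefinite")
    }
    if (length(object@traitNames) != t)
        msg <- c(msg, "traitNames must match the number of architectures")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated data set
#'
#' @slot h2 realized genomic heritability per trait (variance of true
#'   genetic values over variance of phenotypes), per population
#' @slot qtl data.frame of true QTL marker assignments and effects
#' @slot geneticCorr the target genetic correlation matrix
#' @slot geneticValues matrix of per-individual true genetic values
#'   (individuals x traits)
#' @export
setClass("SimTruth",
         representation(h2 = "matrix", qtl = "data.frame",
                        geneticCorr = "matrix", geneticValues = "matrix"))

#' MAF filter report
#'
#' @slot markersIn,markersRemoved,markersOut marker counts
#' @slot threshold the MAF threshold applied (markers with MAF strictly
#'   below it are removed)
#' @slot byPopulation whether filtering was evaluated per population
#' @slot perPopulation named list of retained marker ids per population
#'   (empty unless byPopulation)
#' @export
setClass("FilterReport",
         representation(markersIn = "integer", markersRemoved = "integer",
                        markersOut = "integer", threshold = "numeric",
                        byPopulation = "logical", perPopulation = "list"))

setValidity("FilterReport", function(object) {
    if (object@markersIn - object@markersRemoved != object@markersOut)
        "markersIn - markersRemoved must equal markersOut" else TRUE
})

#' Two-locus joint genotype-class distribution under repeated selfing
#'
#' The exact joint distribution of the 3x3 genotype classes
#' (hom-ref, het, hom-alt at each of two linked loci) in generation
#' F_t of a selfing series started from the coupling F1 heterozygote,
#' with per-meiosis recombination fraction r between the loci.
#'
#' @slot r recombination fraction in [0, 0.5]
#' @slot t generation index (2 = F2, 3 = F3, ...)
#' @slot table 3x3 joint probability table, rows = locus A class,
#'   columns = locus B class, classes ordered (0, 1, 2)
#' @export
setClass("SelfingJoint",
         representation(r = "numeric", t = "integer", table = "matrix"))

setValidity("SelfingJoint", function(object) {
    msg <- character()
    if (object@r < 0 || object@r > 0.5) msg <- c(msg, "r must be in [0, 0.5]")
    if (object@t < 2L) msg <- c(msg, "t must be >= 2")
    tb <- object@table
    if (!all(dim(tb) == c(3, 3))) msg <- c(msg, "table must be 3x3")
    else {
        if (any(tb < -1e-12)) msg <- c(msg, "table entries must be >= 0")
        if (abs(sum(tb) - 1) > 1e-9) msg <- c(msg, "table must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' Maximum-likelihood recombination-fraction estimate
#'
#' @slot rHat ML estimate of the recombination fraction, in [0, 0.5]
#' @slot logLik log-likelihood at the optimum
#' @slot nInformative individuals with both loci non-missing
#' @export
setClass("RecombEstimate",
         representation(rHat = "numeric", logLik = "numeric",
                        nInformative = "integer"))

#' Linkage map: ordered markers with cumulative cM positions
#'
#' @slot positions data.frame with columns `marker`, `chrom`, `cM`;
#'   cM is non-decreasing within a chromosome and starts at 0
#' @slot dropped character vector of marker ids dropped during
#'   construction (adjacent recombination fraction above the cut-off)
#' @slot generation the F_t generation index the map was estimated from
#'   (NA for consensus maps)
#' @export
setClass("LinkageMap",
         representation(positions = "data.frame", dropped = "character",
                        generation = "integer"))

setValidity("LinkageMap", function(object) {
    pos <- object@positions
    if (!all(c("marker", "chrom", "cM") %in% names(pos)))
        return("positions must have columns marker, chrom, cM")
    for (ch in unique(pos$chrom)) {
        cm <- pos$cM[pos$chrom == ch]
        if (length(cm) && abs(cm[1]) > 1e-9)
            return("first marker of each chromosome must sit at 0 cM")
        if (any(diff(cm) < -1e-9))
            return("cM positions must be non-decreasing within a chromosome")
    }
    TRUE
})

#' Interval-mapping scan grid
#'
#' Per evaluation position, the conditional genotype-class probabilities
#' of every individual given the flanking markers.
#'
#' @slot positions data.frame with `chrom`, `cM` per grid position
#' @slot p0,p1,p2 matrices (individuals x positions) of conditional
#'   probabilities of classes 0, 1, 2; each row triple sums to 1
#' @slot individuals individual ids (row order of the probability matrices)
#' @slot t generation index used for the conditioning model
#' @export
setClass("ScanGrid",
         representation(positions = "data.frame", p0 = "matrix", p1 = "matrix",
                        p2 = "matrix", individuals = "character", t = "integer"))

#' Composite-interval-mapping scan result
#'
#' @slot table data.frame with `chrom`, `cM`, `lod` (and `degenerate`
#'   flag for capped perfect-fit positions)
#' @slot cofactors marker ids used as background cofactors
#' @slot windowCM cofactor exclusion window (cM)
#' @slot threshold genome-wide LOD threshold (NA until set)
#' @slot alpha significance level of the threshold
#' @slot nPerm permutations used for the threshold
#' @export
setClass("QTLScanResult",
         representation(table = "data.frame", cofactors = "character",
                        windowCM = "numeric", threshold = "numeric",
                        alpha = "numeric", nPerm = "integer"))

#' Genomic relationship matrix
#'
#' @slot G g-by-g relationship matrix (VanRaden linear kernel)
#' @slot normConstant the normalization constant 2*sum(p(1-p)) used
#' @slot excluded ids of monomorphic markers excluded from the kernel
#' @export
setClass("GRM",
         representation(G = "matrix", normConstant = "numeric",
                        excluded = "character"))

#' Fitted single-trait GBLUP model
#'
#' @slot beta fixed-effect estimates (intercept or population means)
#' @slot u genetic values (BLUP) for all individuals in the relationship
#'   matrix, including any unphenotyped ones
#' @slot sigma2u,sigma2e genetic and residual variance components (REML)
#' @slot h2 genomic heritability sigma2u / (sigma2u + sigma2e)
#' @slot logLik restricted log-likelihood at the optimum
#' @slot fitted fitted values X beta + u for phenotyped individuals and
#'   predictions for unphenotyped ones
#' @slot model model tag
#' @export
setClass("GPFit",
         representation(beta = "numeric", u = "numeric", sigma2u = "numeric",
                        sigma2e = "numeric", h2 = "numeric", logLik = "numeric",
                        fitted = "numeric", model = "character"))

setValidity("GPFit", function(object) {
    msg <- character()
    if (object@sigma2u < 0 || object@sigma2e < 0)
        msg <- c(msg, "variance components must be >= 0")
    if (object@h2 < 0 || object@h2 > 1)
        msg <- c(msg, "h2 must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Fitted whole-genome regression (BayesB / multi-trait BayesC-pi)
#'
#' @slot effects posterior mean marker effects (m x t; t = 1 for BayesB)
#' @slot inclusionProb posterior inclusion probability per marker
#' @slot pi posterior mean of the exclusion-mass parameter
#' @slot beta posterior mean fixed effects (p x t)
#' @slot sigma2e posterior mean residual variance (t x t for multi-trait)
#' @slot chain list of chain settings (iterations, burn-in, thin, seed)
#' @slot model model tag
#' @export
setClass("MarkerEffectFit",
         representation(effects = "matrix", inclusionProb = "numeric",
                        pi = "numeric", beta = "matrix", sigma2e = "matrix",
                        chain = "list", model = "character"))

#' Fitted multi-trait GBLUP model
#'
#' @slot K t-by-t genetic covariance matrix
#' @slot R t-by-t residual covariance matrix
#' @slot geneticCorr genetic correlation matrix (K scaled to unit diagonal)
#' @slot h2 per-trait genomic heritability K_ii / (K_ii + R_ii)
#' @slot B fixed-effect estimates (p x t)
#' @slot U predicted genetic values (n x t)
#' @slot converged whether the EM iteration met the tolerance
#' @slot iterations EM iterations used
#' @export
setClass("MultiTraitFit",
         representation(K = "matrix", R = "matrix", geneticCorr = "matrix",
                        h2 = "numeric", B = "matrix", U = "matrix",
                        converged = "logical", iterations = "integer"))

#' Cross-validation result
#'
#' @slot perRepeat Pearson correlation between observed and predicted
#'   values over all held-out individuals, one per repeat
#' @slot accuracy mean of the per-repeat correlations
#' @slot sd standard deviation over repeats
#' @slot perFold data.frame of per-fold details (repeat, fold, r, n)
#' @slot scheme list recording folds, repeats, seed, stratification
#' @export
setClass("CVResult",
         representation(perRepeat = "numeric", accuracy = "numeric",
                        sd = "numeric", perFold = "data.frame",
                        scheme = "list"))
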