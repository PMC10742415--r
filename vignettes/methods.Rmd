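---
title: "Models and methods in selfGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in selfGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`selfGP` analyses biparental breeding populations advanced by repeated
self-pollination, the design used in medicinal-plant programmes such as
red perilla: several crosses sharing one elite parent, selfed to F3 and
F4 with selection, genotyped at a few hundred to ~1,500 biallelic SNPs
per population and phenotyped for compound contents and agronomic
traits.  This vignette records the statistical models, the parameters
that matter, the numerical choices, and the design decisions that were
genuinely open.

## Genotype coding and containers

All genotypes are coded relative to a designated reference parent:
0 = homozygous for that parent, 1 = heterozygous, 2 = homozygous for
the other parent.  The central container, `MarkerMatrix`, extends
`SummarizedExperiment` with markers as rows and individuals as columns;
marker metadata carry the chromosome and cM (and optionally bp)
position, individual metadata the population (cross) label, generation
and pedigree line.  The allotetraploid perilla genome is treated as
diploid-behaving markers, exactly as the 0/1/2 coding implies.

MAF filtering removes a marker when its minor allele frequency is
*strictly* below the threshold (a MAF exactly at the threshold is
retained), evaluated either pooled or within each population; in the
per-population mode each population keeps its own marker set, which is
why different crosses retain different marker counts.  Missing scores
are imputed by the per-marker, per-population mode, with ties broken
toward the lower score (a deterministic rule, stated rather than
clever); LD-aware imputation is deliberately out of scope, and markers
missing in more than 90% of a population are refused.

## The F_t two-locus selfing model

The backbone of both map construction and interval mapping is the exact
joint distribution of genotype classes at two linked loci in generation
F_t.  The F1 is the coupling double heterozygote AB/ab; each selfing
generation draws two independent gametes per diplotype, with
per-meiosis recombination probability r between the loci.  The
two-locus diplotype space has ten unordered states, so the distribution
is propagated exactly through a 10×10 transition matrix and
marginalized to the 3×3 class table.  Its single-locus marginal has
heterozygote fraction (1/2)^(t−1) — the 3:2:3 ratio at F3 — for every
r, and the table is symmetric under simultaneously swapping the two
homozygote classes at both loci.  The implementation is verified
against an independent brute-force enumeration over gamete-inheritance
patterns for t ∈ {2, 3, 4} to 10⁻¹².

**Phase.**  Unphased 0/1/2 classes cannot separate linkage phase from
r: recoding which parent scores 0 at one locus turns coupling data into
repulsion data, and for t ≥ 3 the repulsion table is *not* the r → 1−r
mirror of the coupling table (the repulsion heterozygote keeps
producing coupling gametes at rate r in later generations).  The
exported estimator `estimateRecombination()` is therefore phase-unaware
by construction: it maximizes the likelihood jointly over r and the F1
phase, making the estimate exactly invariant to how either locus is
coded.  Inside `buildMap()` the coupling-only likelihood is used
instead, because all scores share one reference parent and adjacent
pairs are coupling by construction; a marker whose coding is
inconsistent then shows up as apparent repulsion, drives the coupling
estimate to the 0.5 boundary, and is dropped by the r > 0.499 rule.

**Optimization.**  r is profiled on a 0.01 grid over [0, 0.5] and
refined by bounded scalar search (`optimize`, tolerance 10⁻⁶), keeping
a grid end-point when it is at least as good — a 1-D bounded problem
needs no EM.  Grid tables are cached per generation.

## Linkage maps

Marker order is fixed to the reference order; no ordering or grouping
is attempted (the study design maps reads to a reference genome, so
order is known).  Along each chromosome, adjacent-pair r̂ is estimated,
pairs with r̂ > 0.499 drop the offending marker (logged on the result),
and cumulative positions are running sums of Kosambi distances
d = 25·ln((1+2r)/(1−2r)) cM from the chromosome's first retained
marker.  Whether the source protocol estimated r from adjacent pairs
only or from all pairs is not stated; adjacent pairs are sufficient for
cumulative maps and are what is implemented.

The consensus map across populations pools (shared marker rank,
population cM) points per chromosome; the consensus position is the
per-rank mean plus a loess fit (degree 1, default span 0.3,
configurable — no span is stated in the source protocol) of the pooled
deviations from those means, which vanishes when the maps coincide and
irons out rank-local disagreements and subset-marker jumps.  Loess can
be locally non-monotone, so positions are projected to the nearest
monotone sequence by pool-adjacent-violators (`isoreg`) and shifted to
start at 0 cM.  The predictor is the shared rank, not physical bp,
because rank is what the fixed reference order guarantees to be common.

F4 data can be mapped with t = 4 probabilities, but the pipeline
default reproduces the protocol's choice: the map is built from F3 and
reused for F4.

## Composite interval mapping

`conditionalProbs()` computes, at each grid position (default step
1 cM), each individual's conditional class probabilities given the two
flanking markers, combining the F_t joint tables of (left, position)
and (position, right) with r from the Kosambi inverse of the cM gaps
and normalizing over the three classes.  A missing flank falls back to
single-flank conditioning; no flanks, to the F_t marginal.  A position
coinciding with a scored marker gets probability 1 on the observed
class (the r = 0 table enforces this automatically).

The scan is a Haley–Knott-style regression: phenotype on expected
additive dosage and heterozygote probability (2 df — selfing
generations retain heterozygotes, and the source protocol does not
state its scan's df), plus cofactor marker scores, excluding cofactors
within a 10 cM window of the position on the same chromosome.
LOD = (n/2)·log₁₀(RSS₀/RSS₁) against the same-cofactor null.  This is
a documented approximation to full-mixture EM interval mapping; it
admits exact small-case oracles (at a marker with k = 0 cofactors it
equals the single-marker regression LOD) and behaves like
regression-based CIM at these scales.  Cofactors (default five, the
protocol's setting) come from forward stepwise least squares, are
deterministic given the data, and are *fixed* across permutations by
default — the standard practical choice; a strict mode re-selects them
per permutation.  Collinear design columns are dropped by
rank-revealing QR; a perfect fit is capped at LOD 50 with a degeneracy
flag.

Genome-wide thresholds are empirical (1−α) quantiles (type-7) of the
per-permutation maximum LOD; α defaults to 0.05 (the protocol states
10,000 permutations but never the level), and fewer than 100
permutations are refused as too unstable.  "QTLs" are reported as
contiguous above-threshold segments, each represented by its peak —
the counting convention is documented because grid-position counts,
peaks and intervals can differ severalfold.

## Genomic prediction

**GRM.**  G = CCᵀ/c with columns centered by 2p.  Two normalization
constants are offered: the textbook VanRaden c = 2Σp(1−p) (default),
and c = Σ observed marker variances ("observed"), which makes the mean
diagonal exactly 1 in any population.  The distinction matters here:
selfing leaves a heterozygote deficit (F ≈ 0.5 at F3), inflating
marker variances by 1+F, so the binomial constant yields mean
diag(G) ≈ 1.5 and the ratio σ²ᵤ/(σ²ᵤ+σ²ₑ) then understates the realized
heritability by up to ~0.1.  The pipeline therefore uses the observed
normalization for F_t panels; the constant used is recorded in the
`GRM` object.  Pooled allele frequencies are used for the
combined-population G (per-population frequencies are available by
subsetting), monomorphic markers are excluded with a log entry, and a
non-PSD G gets a documented 10⁻⁶ ridge.

**Single-trait GBLUP.**  y = Xβ + u + ε with u ~ MVN(0, Gσ²ᵤ).  REML
(not ML) via one eigendecomposition of G: the restricted likelihood is
profiled over λ = σ²ᵤ/σ²ₑ on a 41-point log grid spanning 10⁻⁵–10⁵ and
refined by bounded search; boundary σ²ᵤ is clamped at 10⁻⁸ × phenotypic
variance.  In per-population models X is an intercept; in
combined-population models it is the population-indicator design (one
mean per cross).  Individuals with missing phenotype are predicted
through the joint relationship matrix,
u = σ²ᵤ·G[,obs]·V⁻¹(y − Xβ̂) — the standard GBLUP prediction, which is
also how cross-validation holds out folds.  A phenotype with zero
variance is an error (no estimable model), rather than a silent h² = 0.

**BayesB.**  y = Xβ + Wa + ε with a per-marker mixture prior: point
mass at zero with probability π and a scaled-t slab, implemented as a
normal with marker-specific variance under a scaled-inverse-χ² prior
(df 5; scale from a phenotypic-variance heuristic targeting half the
variance across the expected included markers).  π gets a Beta(9, 1)
prior on the *exclusion* mass — a sparse start with ~10% of markers in
the model — and is updated.  The Gibbs sampler is compiled
(Rcpp/Armadillo) and uses R's RNG, so chains are bit-reproducible under
a seed; defaults are 12,000 iterations with 2,000 burn-in, and the
reduced chains used in tests (1,200–2,000 iterations) are stated where
used.  Non-finite samples abort with the iteration index.

**Multi-trait GBLUP.**  vec(Y) ~ MVN(vec(XB), K⊗G + R⊗Iₙ).  Rotating
by G's eigenvectors makes rows independent with covariance sᵢK + R;
each EM pass additionally diagonalizes (K, R) jointly in trait space,
so the GLS update of B and the E/M-steps are elementwise — iterations
cost O(n·t²).  Iteration stops at relative change < 10⁻⁶ or 500
passes; non-convergence is flagged on the result and the last iterate
returned (duplicated traits, for example, converge slowly toward a
singular K with correlation 1 — flagged, not fatal).  EM-REML in the
eigenbasis was chosen over average-information REML for its monotone,
testable ascent.  Genetic correlations are K scaled to unit diagonal;
per-trait h² is Kᵢᵢ/(Kᵢᵢ+Rᵢᵢ).

**Multi-trait BayesCπ.**  One shared inclusion indicator per marker;
included markers get a t-variate normal effect whose covariance has an
inverse-Wishart prior updated from the sampled effects; the residual
covariance is likewise inverse-Wishart updated.  With t = 1 this is
single-trait BayesC with estimated π.

## Cross-validation

Default 10-fold × 10 repeats.  Per repeat, all held-out predictions are
pooled and one Pearson correlation computed; the accuracy is the mean
over repeats and its uncertainty the SD over repeats.  The source
protocol's "for each cross validation" is ambiguous between this
pooled reading and a per-fold average; the pooled reading is the
default and the per-fold alternative is a flag
(`perFoldCorrelation = TRUE`).  The GRM is computed once over all
individuals — standard GBLUP practice; only relatedness, never
phenotypes, crosses the fold boundary.  Folds are stratified by
population when labels are given, with fold sizes differing by at most
one per stratum; a stratum smaller than the fold count falls back to
unstratified assignment with a warning.  Whether the original analysis
stratified its combined-population CV is unstated; stratification is
the package default because it keeps population means estimable in
every training fold.

## The simulator: what it emulates, and what it does not

`simulateBreedingProgram()` reproduces the programme design: crosses
sharing one reference parent (additional donor parents differ at a
random fraction of markers — default 0.7 — so crosses segregate at
different, overlapping marker subsets, as the per-population marker
counts in such programmes show); F2 of 200 lines, 100 selected, three
seeds per line to F3; 100 F3 lines selected half from field-grown and
half from not-grown material, three seeds per line to F4.  Selection
defaults to random — the programme selected partly "to maintain
diversity" without a stated criterion — and truncation on a trait's
true genetic value is available.  Crossovers are a Poisson process
(mean = length in Morgans, uniform positions, no interference), i.e.
the Haldane model, even though maps are estimated with Kosambi: the
simplest generative model suffices because what the tests assert is
recombination-fraction recovery, and the Kosambi/Haldane discrepancy
is below ~2 cM for r ≤ 0.2.

Phenotypes are population mean + genetic value + noise.  Large-QTL
effects attach to the marker nearest the stated (chromosome, cM)
position, so truth stays expressible in marker coordinates; polygene
effect vectors across traits are drawn multivariate normal and the
polygenic component is then recolored in trait space so its realized
covariance matches the target exactly — necessary because
chromosome-scale LD in an F_t cross otherwise makes the realized
genetic correlation fluctuate far beyond the target, and legitimate
because a trait-space transform keeps effects exactly marker-attached.
Noise is likewise decorrelated from the genetic values and
variance-calibrated so the realized heritability equals the target;
targetH2 = 0 zeroes the genetic values and targetH2 = 1 the noise.  A
presence/absence architecture (one parental homozygote at a designated
locus abolishes the trait) reproduces the behaviour of compounds that
one donor simply lacks.  Population means default to offsets of about
half a within-population SD — large enough to exercise the n×3
fixed-effect design, small enough not to dominate pooled correlations.

The simulator does **not** model sequence-level data (reads, ddRAD
fragments), genotyping error (missingness is configurable but defaults
to 0), epistasis beyond the presence/absence rule, crossover
interference, or genotype-by-environment effects.  Tests passing on
simulated data therefore certify the estimators under a clean additive
world with known truth — not robustness to assay artefacts or
non-additive genetics.

## Problem sizes used by the tests

The test suite exercises the estimators at the sizes the methods are
meant for, scaled to run quickly: single populations of ~300 F3
individuals; genomes of 20 chromosomes × 70 cM with 600–1,000 markers
for heritability, genetic-correlation and prediction checks (50, 30 and
30 replicates respectively); a 5-chromosome genome for the
permutation-threshold calibration (100 null scans at 200 permutations)
and QTL-localization power (50 scans); and the full three-cross demo
pipeline (3 × 300 individuals, 600 markers) run twice to verify
bit-identical reproduction.  Bayesian chains in tests use 1,200–2,000
iterations; production defaults are 12,000.

## Known limitations

- The class-level likelihood estimates r only up to phase; with the
  phase-unaware estimator this is by design, but r̂ near 0.5 is weakly
  identified and single noisy markers inflate adjacent gaps when they
  escape the 0.499 cut (an independent-noise marker is caught only
  ~70% of the time; a phase-inconsistent one always).
- CIM here is regression-based, not full-mixture EM; with heavy
  segregation distortion or strong dominance the conditional-expectation
  approximation degrades first.
- GBLUP's h² for strongly oligogenic traits understates the realized
  value (a relationship matrix spreads single-locus signal genome-wide);
  this is a property of the model, visible in the package's own
  comparisons, not a bug.
- No across-population prediction (train on one cross, test on
  another) and no multiple-QTL model fitting or effect-interval
  estimation; both are genuine extensions, not oversights.
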