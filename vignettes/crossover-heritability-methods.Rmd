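---
title: "Methods: crossover detection and the quantitative genetics of recombination rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover detection and the quantitative genetics of recombination rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(xoverherit)
```

# Scope

`xoverherit` studies individual variation in meiotic recombination rate in
SNP-genotyped, multi-generation pedigrees. The phenotype is the autosomal
crossover count (ACC): the number of crossovers detected in one gamete that
a focal individual (FID) transmits to one offspring. An FID with several
genotyped offspring contributes several ACC measures, so every model
downstream is a repeated-measures model. The package covers the whole
analysis path: crossover detection from sub-pedigree phasing, genomic and
pedigree relatedness matrices, REML animal models and cross-sex bivariate
models, repeated-measures genome-wide association with genomic control and
an LD-based significance threshold, regional heritability mapping,
genotype and haplotype effect sizes, and sex-balanced resampling. A
forward-in-time pedigree meiosis simulator with a known architecture makes
every stage testable against truth.

# Crossover detection

## Sub-pedigrees and phasing

For each FID-offspring pair, the five-member sub-pedigree (FID, its mate,
its sire and dam, and the offspring) makes the transmitted gamete
phase-resolvable. Genotypes are held as 0/1/2 dosages of a reference "B"
allele. A SNP yields a grandparental origin call when three conditions
meet: the FID is heterozygous; the allele the FID transmitted is
determined (offspring homozygous, or offspring heterozygous with the mate
homozygous); and exactly one FID parent can have carried that allele. A
parent with a missing genotype is treated as able to carry either allele,
so a call is still made when the *other* parent demonstrably lacks the
transmitted allele. This is the conservative subset of trio-phasing logic:
no multi-marker inference is attempted, and anything ambiguous stays
uncalled.

Before phasing, parent-offspring genotype pairs sharing no allele
(opposite homozygotes) are masked in both members; if any parent-offspring
pair in the sub-pedigree mismatches at more than 0.1% of compared loci,
the whole sub-pedigree is discarded. Note the threshold is a *fraction*:
on small test panels a single mismatch can exceed it, which is faithful
behavior, not a bug.

## Calling and quality control

Crossovers are switches of grandparental origin between consecutive
informative SNPs. QC applies in a fixed order:

1. raw call;
2. gametes with a raw ACC above 60 are discarded outright (pervasive
   phasing error); the screen uses the raw count, before any masking;
3. phase runs consisting of a single SNP are masked (one pass) and
   crossovers re-called;
4. any internal run whose flanking informative markers (last SNP of the
   preceding run, first SNP of the following run) span 10 cM or less is
   masked; because masking merges the flanking runs, this step iterates to
   a fixed point;
5. per-chromosome counts and ACC are computed, and each crossover is
   reported as an interval between its flanking SNPs, never a point.

A run touching a chromosome end is bounded by only one switch and is never
treated as a double crossover. Masking can only reduce counts, and ACC is
invariant to reversing the SNP order within a chromosome; both properties
are asserted in the test suite.

Two consequences of these rules are worth knowing. First, the >60 screen
discards the *gamete record*, not every record of that FID: the unit under
QC is crossovers per gamete, and discarding an individual's other,
well-phased gametes would throw away information (the alternative reading
of "individuals ... were removed" is noted but not implemented). Second, a
true crossover falling inside the outermost marker interval of a
chromosome produces a terminal single-SNP run and is masked by rule 3; it
is genuinely indistinguishable from a one-SNP phasing artifact. The caller
is therefore exact only for crossovers separated by more than the
double-crossover span from each other and clear of the terminal marker
intervals — the acceptance suite verifies 100% exactness on precisely that
set, and treats the rest as the method's documented resolution limit.

# Relatedness matrices

The genomic relatedness matrix (GRM) uses the standard frequency-scaled
cross-product of centered dosages, with missing genotypes mean-imputed to
`2p`. By default the diagonal is replaced by `1 + F`, where `F` is the
variance-based genomic inbreeding coefficient — the sampling-error-corrected
form appropriate when genotyped and causal loci are assumed to share a
frequency spectrum. Because this replaced diagonal is not a Gram-matrix
diagonal, the GRM can have small negative eigenvalues on finite panels;
`ensure_pd()` shifts the diagonal just enough to restore positive
definiteness (the shift is recorded in the `pd_shift` attribute and only
warned about when large). The `diag(GRM) - 1 = F` identity holds exactly
up to the declared ridge and shift.

For 20-SNP windows the corrected diagonal is far too noisy to factorize
(rank-20 matrices with shifts larger than 1 are common), so the regional
models use `adjust = FALSE`: the plain cross-product diagonal, positive
semidefinite by construction. The window/rest decomposition then satisfies
the exact identity `m_all * K_all = m_win * K_win + m_rest * K_rest`,
which is how the rest-of-genome GRM is built (it excludes only the focal
window's SNPs, not the whole chromosome).

The pedigree numerator relationship matrix uses the tabular method in
topological order; cycles are an error.

# REML engine

All models have the form `y = Xb + Zu + e` with `u` indexed by
individuals (or individuals-by-sex) and a diagonal residual. Because `Z`
is an indicator matrix, every REML quantity reduces to q-dimensional
algebra via the Woodbury identity (q = number of levels), so a fit costs
O(q^3) per iteration instead of O(n^3). The maximizer is
average-information REML with step-halving; a proposed step that fails to
improve the restricted likelihood is halved up to 25 times, then an
EM-style step is tried, so the accepted trajectory is monotone by
construction. Components are constrained non-negative at a boundary of
1e-10 times the phenotypic variance and pinned there after pushing
negative twice; covariance components (the cross-sex additive covariance)
are unconstrained in sign. Convergence is an absolute change in restricted
log-likelihood below 1e-8 within 200 iterations. Standard errors come from
the inverse average-information matrix; variance-ratio standard errors use
the delta method with the full component covariance. Random terms sharing
a level set are merged into one covariance block (`va*K + vpe*I` is the
exact distribution of the summed effects), which keeps q equal to the
number of individuals in the standard animal model.

The cross-sex bivariate model treats female and male ACC as two traits on
disjoint individuals, with sex-specific additive variances, a cross-sex
additive covariance, sex-specific permanent-environment and residual
variances, and per-trait fixed effects (intercept plus the genomic
inbreeding coefficient; the per-trait fixed-effect structure is the
package's choice, as only intercept-level covariates are available per
sex). Positive definiteness of the implied covariance does *not* bound the
genetic correlation when the GRM is near-diagonal, so all four modes
(free, r fixed at 0, r fixed at 0.999, equal additive variances with free
r) are fitted by bounded profile optimization (Nelder-Mead on log
variances with the correlation mapped through tanh), which enforces
|r| < 1 exactly. Constrained modes are compared to the free fit with a
1-df likelihood-ratio test — 1 df throughout, as is conventional for a
single constrained parameter; for variance components tested at the
boundary this is conservative, which the null-calibration test confirms
(rejection rate at or below nominal).

# Association scans

The genome scan is the two-stage repeated-measures design: the null animal
model (GRM + permanent environment + residual; sex and inbreeding as fixed
effects) is fitted once, its covariance frozen, and each SNP's mean-imputed
dosage tested as a single generalized-least-squares covariate with a 1-df
chi-square. A scan oracle test checks the GLS coefficient against an
explicit dense-matrix solve. Genomic control divides the statistics by
`lambda` (observed median chi-square over 0.4549364) only when
`lambda > 1`; deflation is never applied, but `lambda` is always reported.
The trans scan refits the null model per chromosome with the response ACC
minus that chromosome's crossovers, so cis-acting artifacts cannot drive
it.

The significance threshold divides alpha by an effective number of tests.
SNPs are processed per chromosome in map order in non-overlapping blocks
of 50, each block contributing the Moskvina-Schmidt-type reduction
`1 + sum_i sqrt(1 - max_{j<i} r2_ij)` from its pairwise allelic
correlations. The originating software's exact arithmetic (window overlap,
formula variant) is not recoverable, so this package states its formula
explicitly and exposes the block size; duplicated SNPs halve the count and
independent SNPs reproduce it, which brackets the intended behavior.

Regional heritability mapping partitions additive variance between a
20-SNP sliding window GRM (10-SNP overlap) and the rest-of-genome GRM,
testing the window term by a 1-df LRT against the model without it.
Chromosome ends append a truncated window when at least half a window of
trailing SNPs would otherwise start uncovered; short chromosomes become a
single whole-chromosome window. The genome-wide threshold is alpha divided
by half the window count (the overlap correction). Fine mapping rescans a
significant region plus a 5 Mb margin with windows of 20, 10 and 6 SNPs
advancing one SNP at a time; those p-values are labeled exploratory.

# Effect sizes and resampling

Genotype effects fit the three-class genotype as a fixed factor with a
relatedness random effect, permanent environment and residual; the
baseline is the homozygote of the alphabetically first allele, classes
with no records are dropped, and classes with fewer than 10 records are
flagged as sampling-noisy. Haplotype effects collapse all non-focal
haplotypes into one pseudo-allele and recode diplotypes by focal-copy
number; the baseline class is the common non-carrier diplotype, so the
heterozygote solution estimates the per-copy effect — this matches how
published effect-size tables are laid out (the focal-homozygote class is
typically rare), and takes precedence over the alternative labeling in
which the focal homozygote would be the intercept. Haplotypes are testable
when they exceed 10 copies; both the copy tally and the carrier tally are
reported, since the two differ for homozygous carriers. Phase comes from
the simulator's truth or trio resolution; population statistical phasing
is out of scope.

Sex-balanced resampling draws a fixed number of gamete records (default
482) with replacement within each sex, recomputes any statistic
(heritability, a SNP's chi-square, a window's LRT) on each replicate, and
compares the per-sex replicate means with a Welch t-test (Satterthwaite
degrees of freedom). The resampling unit is the *measure*, matching how
such comparisons are defined for repeated-measures data; an
individual-level mode exists behind a flag because records of one FID are
not independent.

# The simulator: what it does and does not emulate

`sim_config()` defaults describe a wild-deer-like study scaled to desk
size: 33 acrocentric autosomes of 76 cM (about 25 Morgans in total, so
mean ACC equals the sex means), sex-dimorphic means of 26.6 (females) and
22.2 (males), founder allele frequencies uniform on (0.05, 0.5), and an
additive architecture for crossover propensity of one major locus
(v_qtl = 3), a polygenic background (v_poly = 0.5) and a per-gamete
residual (v_resid = 2) — together roughly 0.11 of a phenotypic variance
that is dominated by meiotic (Poisson) noise, in line with the low
heritabilities reported for this trait. Genotyping error (0.001) flips a
single allele; missingness (0.005) masks calls. Every stochastic function
requires an explicit seed; there is no default seed.

Per meiosis, each chromosome's crossover count is Poisson with mean
proportional to chromosome length and scaled so the genome-wide
expectation equals the parent's propensity (sex mean + breeding value +
gamete residual, floored at 0.1); positions are uniform on the cM axis.
There is no crossover interference and no obligate crossover (an optional
switch adds the latter); real mammalian meiosis has both, so simulated
double crossovers at short range are *more* common than in real data —
conservative for testing the short-double filter. The propensity acts on
the count scale through a linear link with a floor rather than a log link,
because the downstream animal models are linear on observed counts.
Founders are unlinked and unrelated, so background LD is purely familial;
tests of LD-driven behavior construct their LD explicitly. Passing tests
therefore demonstrate correctness of the algorithms under a known additive
architecture — not robustness to interference, population LD structure, or
non-additive variation.

A design note on the spec of the map: a zero-length chromosome is rejected
as an invalid configuration (the map contract) rather than producing
zero-crossover chromosomes.

# Problem sizes used in the checks

The test suite exercises: crossover-caller exactness on a 20-chromosome,
100-SNP-per-chromosome genome (about 1,500 simulated gametes, of which the
several hundred with well-separated, interior crossovers form the
exactness set); artifact filtering at a 0.1% genotyping error rate on the
same geometry; heritability recovery at 2,000 SNPs with about 1,680
records on 420 individuals, 20 replicates (2,000 markers are needed for
the GRM to track pedigree relatedness without attenuating the additive
variance — at 800 markers the estimate is visibly attenuated, which is a
property of marker-based heritability, not of the solver); a 2,000-SNP
null scan plus 20 planted-locus scans; 10 regional scans of 18 windows;
and resampling at 482 measures and 100 replicates. These sizes are the
package's calibration choices: large enough that Monte-Carlo error is
small against the tested tolerances, small enough to run routinely.

# Known limitations

* No crossover interference in the simulator, and no sex-specific maps.
* The caller's resolution is bounded by informative-marker density; with
  sparse informative SNPs real crossovers near chromosome ends and tight
  double crossovers are systematically missed (by design of the QC rules).
* Marker-based heritability attenuates when the SNP panel is sparse
  relative to pedigree depth.
* The effective-number-of-tests reduction is one member of a family of
  such formulas; it is stated exactly and tested for its limiting
  behaviors, but no claim is made of matching any external program
  bit-for-bit (the same holds for the GRM diagonal adjustment).
* X-chromosome models, dominance GRMs, and population statistical phasing
  are out of scope.
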