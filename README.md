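# xoverherit

Crossover detection and the quantitative genetics of recombination rate in
SNP-genotyped pedigrees.

Meiotic recombination rate varies between individuals, and part of that
variation is heritable. In a multi-generation pedigree genotyped on a SNP
chip, the rate can be measured directly: for each focal individual (FID)
and each of its genotyped offspring, the five-member sub-pedigree (FID,
mate, FID's sire and dam, offspring) phases the transmitted gamete, and
switches in grandparental origin along a chromosome are crossovers. The
resulting phenotype — the autosomal crossover count (ACC), one measure per
gamete — can then be analyzed like any repeated-measures quantitative
trait. This package implements the full analysis path for researchers
working on the genetic architecture of recombination in pedigreed (often
wild) populations:

* **Crossover calling** (`build_subpedigrees`, `screen_mendelian`,
  `phase_gamete`, `call_crossovers`, `call_acc`): trio-logic phasing with a
  Mendelian screen (sub-pedigrees with >0.1% mismatching loci discarded),
  a >60-crossover gamete screen, masking of single-SNP phase runs, and
  masking of double crossovers spanning ≤10 cM.
* **Relatedness** (`grm`, `allele_freqs`, `pedigree_amatrix`): the
  frequency-scaled genomic relatedness matrix with the
  sampling-error-corrected diagonal 1 + F (F the variance-based genomic
  inbreeding coefficient), GCTA-style text import/export, and the pedigree
  numerator relationship matrix.
* **Variance components** (`reml_fit`, `acc_animal_model`, `heritability`,
  `lrt`, `wald_fixed`, `reml_bivariate`): average-information REML animal
  models `y = Xb + Z1 a + Zr ur + e` with `var(a) = VA * GRM`, heritability
  as `h2 = VA / (VA + Vpe + Ve)`, likelihood-ratio and Wald tests, and
  cross-sex bivariate models with the genetic correlation `rA` free or
  constrained (0, 0.999, equal variances).
* **Association** (`snp_scan`, `trans_scan`, `genomic_control`,
  `keff_threshold`): two-stage repeated-measures GWAS with the GRM as a
  random effect, genomic-control `lambda` (observed over null median
  chi-square), the trans-ACC scan (ACC minus the focal chromosome's
  crossovers), and an LD-based effective number of tests in 50-SNP blocks
  giving the genome-wide threshold `alpha / K_eff`.
* **Regional heritability** (`make_windows`, `fit_window`, `scan_regions`,
  `finemap`): 20-SNP sliding windows (10-SNP overlap) fitting
  `y = Xb + Z1 vi + Z2 vni + Zr ur + e` with a window GRM and a
  rest-of-genome GRM, window LRTs, the overlap-corrected Bonferroni
  threshold `alpha / (n_windows / 2)`, and n−1-overlap fine mapping.
* **Effect sizes** (`genotype_effect`, `extract_haplotypes`,
  `haplotype_effect`, `ld_r2`): genotype-as-fixed-factor animal models and
  focal-haplotype-versus-rest models (testable above 10 copies), with
  allelic-correlation LD.
* **Resampling** (`balanced_resample`): sex-balanced resampling of 482
  measures with Welch t comparisons, to separate real sex differences from
  sample-size artifacts.
* **Simulation** (`sim_config`, `simulate_dataset`, `write_dataset`):
  a forward-in-time pedigree meiosis simulator with known linkage maps,
  Poisson crossover counts whose mean is the parent's crossover propensity
  (sex mean + major-locus effect + polygenic value + gamete residual),
  genotyping error and missingness, plus complete truth tables — so every
  stage above is testable without external data.

## Worked example

Simulate a 20-chromosome genome with a planted major-effect locus, call
crossovers through the full QC pipeline, and run the heritability model
and the genome scan on the called ACC:

```r
library(xoverherit)

cfg <- sim_config(n_chromosomes = 20, snps_per_chromosome = 80,
                  chr_length_cM = 76, spacing = "even",
                  n_founder_pairs = 20, n_offspring_per_mating = 4,
                  n_generations = 4, sex_mean_acc = c(F = 16, M = 13.5),
                  v_qtl = 1.6, v_poly = 0.4, v_resid = 1,
                  genotyping_error_rate = 0.001, missing_rate = 0.005,
                  seed = 42)
sim   <- simulate_dataset(cfg)
calls <- call_acc(sim$genotypes, sim$pedigree, sim$map)
s     <- summarize_acc(calls)
s$summary
#>  group NOBS NFID mean_acc   sd_acc n_xovers
#>   Both  842  225 7.787411 3.001971     6557
#>      F  427  114 8.444965 3.135237     3606
#>      M  415  111 7.110843 2.699482     2951
```

842 gametes from 225 FIDs pass QC; called ACC is higher in females, as
simulated. (Called counts sit well below the simulated truth of ~15 —
only a fraction of SNPs are informative in any one sub-pedigree, so
crossovers near chromosome ends and in sparse stretches are unresolvable;
see the methods vignette.) Now the animal model and scan:

```r
ph <- s$pheno
fq <- allele_freqs(sim$genotypes)
ph$fiii <- as.numeric(fq$fhat3[ph$fid])
K  <- grm(sim$genotypes, fq)
acc_animal_model(ph, K)
#> REML animal model fit: n = 842  logLik = -2037.439879 (converged)
#>
#> Proportions of phenotypic variance:
#>        term      ratio         se
#>  u.additive 0.17069283 0.05717921
#>        u.pe 0.01859675 0.04521792
#>    residual 0.81071043 0.04045500
```

ACC is heritable (h2 = 0.17, SE 0.06) with essentially no
permanent-environment variance, and males average fewer crossovers
(`sexM` solution −1.38, Z = −6.5). The scan finds the planted locus:

```r
sc <- snp_scan(ph, sim$genotypes, K, sim$map)
attr(sc, "lambda")
#> [1] 1.110147
head(sc[order(sc$p), c("snp", "chr", "maf", "effect_B", "chi2", "p")], 3)
#>        snp chr       maf   effect_B     chi2            p
#>  snp_10_40  10 0.3866667  0.9185819 23.10574 1.533326e-06
#>   snp_3_68   3 0.1771300 -0.8671153 11.62474 6.508042e-04
#>  snp_10_69  10 0.4174107  0.6894052 10.83081 9.982475e-04
sim$truth$qtl_snp
#> [1] "snp_10_40"

keff_threshold(sim$genotypes, sim$map, window = 50)$threshold_p
#> [1] 3.224931e-05
```

The top SNP is exactly the simulated causal locus, each B-allele copy
adding ~0.9 called crossovers, and it clears the LD-based genome-wide
threshold. `scan_regions()` and `finemap()` localize the same signal as a
window of additive variance; `genotype_effect()` and `haplotype_effect()`
estimate its per-genotype solutions; `reml_bivariate()` and
`balanced_resample()` probe the sex-specificity of any of these.

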