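# Shared simulated fixtures, built once per test run and cached.
# Per-chromosome crossover rates mirror an acrocentric-autosome genome
# (roughly 0.8 crossovers per chromosome); architectures are scaled so the
# additive share of phenotypic variance is near the 0.1-0.15 seen in wild
# pedigree studies.

sim_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    obj <- switch(name,
      # clean mid-size genome with a planted major locus on chromosome 3
      base = simulate_dataset(sim_config(
        n_chromosomes = 6, snps_per_chromosome = 40, n_founder_pairs = 12,
        n_offspring_per_mating = 4, n_generations = 4,
        sex_mean_acc = c(F = 26, M = 22), v_qtl = 2.2, v_poly = 0.5,
        v_resid = 2, genotyping_error_rate = 0, missing_rate = 0, seed = 101
      )),
      # same geometry with genotyping error and missingness switched on
      noisy = simulate_dataset(sim_config(
        n_chromosomes = 6, snps_per_chromosome = 40, n_founder_pairs = 12,
        n_offspring_per_mating = 4, n_generations = 4,
        sex_mean_acc = c(F = 26, M = 22), v_qtl = 2.2, v_poly = 0.5,
        v_resid = 2, genotyping_error_rate = 0.001, missing_rate = 0.005,
        seed = 102
      )),
      stop("unknown fixture ", name)
    )
    cache[[name]] <- obj
    obj
  }
})

# phenotype table of true ACC per transmitted gamete, with the genomic
# inbreeding covariate attached
acc_pheno <- function(sim) {
  acc <- true_acc_table(sim)
  acc$acc <- acc$acc_true
  fq <- allele_freqs(sim$genotypes)
  acc$fiii <- as.numeric(fq$fhat3[acc$fid])
  acc
}

grm_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(sim, name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <- grm(sim$genotypes)
    }
    cache[[name]]
  }
})
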