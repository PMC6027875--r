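Package: xoverherit
Title: Crossover Detection and the Quantitative Genetics of Recombination
    Rate in Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying individual variation in meiotic
    recombination rate from SNP-genotyped pedigrees. Detects crossovers in
    gametes transmitted from focal individuals to their offspring via
    five-member sub-pedigree phasing with Mendelian screening and
    double-crossover quality control, and models the resulting autosomal
    crossover count (ACC) with genomic-relatedness animal models:
    REML variance components and heritability, cross-sex bivariate genetic
    correlations, repeated-measures genome-wide association with genomic
    control and an LD-based significance threshold, regional heritability
    mapping in sliding SNP windows, haplotype and genotype effect-size
    estimation, and sex-balanced resampling. Includes a forward-in-time
    pedigree meiosis simulator with a known additive architecture of
    crossover propensity so every stage is testable against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
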