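test_that("simulated maps respect geometry and ordering", {
  cfg <- sim_config(n_chromosomes = 3, snps_per_chromosome = 100,
                    chr_length_cM = 80, seed = 1)
  map <- simulate_map(cfg)
  expect_equal(nrow(map), 300)
  for (cc in 1:3) {
    pos <- map$cM[map$chr == cc]
    expect_true(all(diff(pos) > 0))
    expect_true(max(pos) <= 80 && min(pos) >= 0)
    bp <- map$bp[map$chr == cc]
    expect_true(all(diff(bp) > 0)) # bp monotone with cM
  }

  # degenerate single-SNP map
  m1 <- simulate_map(sim_config(n_chromosomes = 1, snps_per_chromosome = 1,
                                seed = 1))
  expect_equal(nrow(m1), 1)

  # even spacing: 101 SNPs over 100 cM -> spacing exactly 1 cM
  me <- simulate_map(sim_config(n_chromosomes = 1, snps_per_chromosome = 101,
                                chr_length_cM = 100, spacing = "even",
                                seed = 1))
  expect_equal(diff(me$cM), rep(1, 100))

  expect_error(sim_config(chr_length_cM = 0, seed = 1), "positive")
  expect_error(sim_config(seed = 1, founder_maf_range = c(0, 0.6)),
               "founder_maf_range")
  expect_error(sim_config(n_chromosomes = 4, qtl_chromosome = 9, seed = 1),
               "qtl_chromosome")
})

test_that("stochastic operations demand an explicit seed", {
  expect_error(sim_config(), "seed")
})

test_that("simulated pedigrees have the focal-individual structure", {
  cfg <- sim_config(n_founder_pairs = 1, n_offspring_per_mating = 2,
                    n_generations = 3, n_chromosomes = 1,
                    snps_per_chromosome = 2, seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_equal(sum(is.na(ped$sire)), 2 * cfg$n_founder_pairs)
  # every non-founder has parents of opposite sexes in the pedigree
  nf <- ped[!is.na(ped$sire), ]
  expect_true(all(ped$sex[match(nf$sire, ped$id)] == "M"))
  expect_true(all(ped$sex[match(nf$dam, ped$id)] == "F"))
  # at least one valid 5-member sub-pedigree exists
  subs <- build_subpedigrees(ped, ped$id)
  expect_gt(nrow(subs), 0)

  # each FID contributes one gamete record per offspring
  cfg4 <- sim_config(n_founder_pairs = 2, n_offspring_per_mating = 4,
                     n_generations = 3, n_chromosomes = 1,
                     snps_per_chromosome = 2, seed = 4)
  ped4 <- simulate_pedigree(cfg4)
  subs4 <- build_subpedigrees(ped4, ped4$id)
  per_fid <- table(subs4$fid)
  expect_true(all(per_fid == 4))
})

test_that("error-free offspring genotypes are Mendelian-consistent", {
  sim <- sim_fixture("base")
  g <- sim$genotypes
  ped <- sim$pedigree
  nf <- ped[!is.na(ped$sire), ]
  opp <- function(a, b) sum(abs(a - b) == 2L, na.rm = TRUE)
  bad <- vapply(seq_len(nrow(nf)), function(i) {
    opp(g[nf$id[i], ], g[nf$sire[i], ]) + opp(g[nf$id[i], ], g[nf$dam[i], ])
  }, 0L)
  expect_true(all(bad == 0L))
})

test_that("transmitted haplotypes match a parental strand between crossovers", {
  sim <- sim_fixture("base")
  tm <- sim$truth$meioses
  # conservation: for a sample of gametes, alleles equal the strand the
  # truth table claims at every SNP
  keys <- unique(paste(tm$parent, tm$offspring, sep = "->"))[1:20]
  for (k in keys) {
    pr <- strsplit(k, "->", fixed = TRUE)[[1]]
    strand <- unlist(true_phase_vectors(sim, pr[1], pr[2]))
    par_h <- rbind(sim$truth$haplo_pat[pr[1], ], sim$truth$haplo_mat[pr[1], ])
    transmitted <- par_h[cbind(strand, seq_along(strand))]
    # the gamete the offspring received from this parent
    got <- if (sim$pedigree$sex[match(pr[1], sim$pedigree$id)] == "M") {
      sim$truth$haplo_pat[pr[2], ]
    } else {
      sim$truth$haplo_mat[pr[2], ]
    }
    expect_identical(unname(transmitted), unname(got))
  }
  # crossover positions are strictly increasing within the chromosome
  expect_true(all(vapply(seq_len(nrow(tm))[1:50], function(i) {
    pos <- tm$positions[[i]]
    all(diff(pos) > 0) && all(pos >= 0 & pos <= sim$config$chr_length_cM)
  }, TRUE)))
})

test_that("true ACC equals the summed per-chromosome crossover counts", {
  sim <- sim_fixture("base")
  acc <- true_acc_table(sim)
  counts <- attr(acc, "counts")
  expect_equal(acc$acc_true, unname(rowSums(counts)))
})

test_that("per-chromosome crossover counts are Poisson with the stated mean", {
  # flat architecture: constant Poisson mean per chromosome
  cfg <- sim_config(n_chromosomes = 10, snps_per_chromosome = 2,
                    n_founder_pairs = 30, n_offspring_per_mating = 6,
                    n_generations = 3, sex_mean_acc = c(F = 25, M = 25),
                    v_qtl = 0, v_poly = 0, v_resid = 0,
                    genotyping_error_rate = 0, missing_rate = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  counts <- as.vector(attr(true_acc_table(sim), "counts"))
  expect_gte(length(counts), 10000)
  lambda <- 25 / 10
  # chi-square goodness of fit against the known mean, pooled tails
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  expp <- stats::dpois(0:kmax, lambda)
  expp[kmax + 1L] <- expp[kmax + 1L] + stats::ppois(kmax, lambda,
                                                    lower.tail = FALSE)
  keep <- expp * length(counts) >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  exp2 <- c(expp[keep], sum(expp[!keep])) * length(counts)
  stat <- sum((obs2 - exp2)^2 / exp2)
  p <- stats::pchisq(stat, df = length(obs2) - 1L, lower.tail = FALSE)
  expect_gt(p, 0.001)
  # mean ACC within 3 SE of the configured sex mean
  acc <- true_acc_table(sim)
  se <- stats::sd(acc$acc_true) / sqrt(nrow(acc))
  expect_lt(abs(mean(acc$acc_true) - 25), 3 * se)
})

test_that("offspring breeding values regress on mid-parent with slope one", {
  cfg <- sim_config(n_chromosomes = 4, snps_per_chromosome = 10,
                    n_founder_pairs = 60, n_offspring_per_mating = 8,
                    n_generations = 3, sex_mean_acc = c(F = 25, M = 25),
                    v_qtl = 1.5, v_poly = 2, v_resid = 0.5,
                    genotyping_error_rate = 0, missing_rate = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  prop <- sim$truth$propensity
  ped <- sim$pedigree
  nf <- ped[!is.na(ped$sire), ]
  bv <- stats::setNames(prop$breeding_value, prop$id)
  mid <- (bv[nf$sire] + bv[nf$dam]) / 2
  off <- bv[nf$id]
  expect_gte(length(off), 2000)
  fit <- stats::lm(off ~ mid)
  slope <- stats::coef(fit)[2]
  se <- sqrt(diag(stats::vcov(fit)))[2]
  expect_lt(abs(slope - 1), 3 * se)
})

test_that("datasets round-trip through the PED/MAP writers and readers", {
  sim <- sim_fixture("noisy")
  d <- withr::local_tempdir()
  paths <- write_dataset(sim, d)
  rt <- read_ped_map(paths[["ped"]], paths[["map"]], alleles = sim$map)
  expect_identical(rt$genotypes, sim$genotypes)
  expect_equal(rt$map$cM, sim$map$cM, tolerance = 1e-6)
  # write -> read -> write is byte-identical
  d2 <- withr::local_tempdir()
  write_ped_map(rt$genotypes, sim$map, sim$pedigree,
                file.path(d2, "data.ped"), file.path(d2, "data.map"))
  expect_identical(readLines(paths[["ped"]]),
                   readLines(file.path(d2, "data.ped")))
  # truth table row count equals simulated meioses
  acc <- utils::read.delim(paths[["acc"]])
  expect_equal(nrow(acc), nrow(true_acc_table(sim)))
  # empty genotype table is an error
  bad <- sim
  bad$genotypes <- sim$genotypes[0, , drop = FALSE]
  expect_error(write_dataset(bad, d), "empty")
})
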