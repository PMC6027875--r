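test_that("haplotype tabulation counts copies and carriers", {
  h1 <- rbind(i1 = c("A", "G"), i2 = c("A", "G"))
  h2 <- rbind(i1 = c("A", "G"), i2 = c("G", "A"))
  colnames(h1) <- colnames(h2) <- c("s1", "s2")
  ht <- extract_haplotypes(h1, h2, c("s1", "s2"))
  ag <- ht$haplotypes[ht$haplotypes$haplotype == "AG", ]
  expect_equal(ag$copies, 3L)
  expect_equal(ag$carriers, 2L)
  # conservation: copies sum to twice the phased individuals
  expect_equal(sum(ht$haplotypes$copies), 2 * nrow(ht$diplotypes))
  # strictly-more-than-10 testability rule
  h1b <- matrix("A", 11, 1, dimnames = list(paste0("x", 1:11), "s1"))
  h2b <- matrix("A", 11, 1, dimnames = list(paste0("x", 1:11), "s1"))
  h2b[11, ] <- "G"
  ht10 <- extract_haplotypes(h1b[1:5, , drop = FALSE],
                             h2b[1:5, , drop = FALSE], "s1")
  expect_false(ht10$haplotypes$testable[
    ht10$haplotypes$haplotype == "A"]) # 10 copies exactly
  ht11 <- extract_haplotypes(h1b[1:6, , drop = FALSE],
                             h2b[1:6, , drop = FALSE], "s1")
  expect_true(any(ht11$haplotypes$testable)) # 11 copies
  # unphased sites exclude the individual
  h1c <- h1; h1c[1, 1] <- NA
  htc <- extract_haplotypes(h1c, h2, c("s1", "s2"))
  expect_equal(htc$n_excluded, 1L)
  expect_equal(nrow(htc$diplotypes), 1L)
})

test_that("simulated truth-phase haplotype counts match a direct tabulation", {
  sim <- sim_fixture("base")
  wsnps <- sim$map$snp[sim$map$chr == 2][5:9]
  ht <- extract_haplotypes(sim$truth$haplo_pat, sim$truth$haplo_mat, wsnps)
  direct <- table(c(
    apply(sim$truth$haplo_pat[, wsnps], 1, paste, collapse = ""),
    apply(sim$truth$haplo_mat[, wsnps], 1, paste, collapse = "")
  ))
  expect_equal(ht$haplotypes$copies,
               unname(as.integer(direct[ht$haplotypes$haplotype])))
})

test_that("genotype effects recover a planted additive allele effect", {
  sim <- sim_fixture("base")
  ph <- acc_pheno(sim)
  A <- pedigree_amatrix(sim$pedigree)
  a_true <- sim$truth$qtl_effect
  gv <- stats::setNames(sim$genotypes[, sim$truth$qtl_snp],
                        rownames(sim$genotypes))
  ge <- genotype_effect(ph, gv, A, fixed = "sex")
  expect_equal(ge$classes$genotype, c("A/A", "A/B", "B/B"))
  het <- ge$classes[ge$classes$genotype == "A/B", ]
  hom <- ge$classes[ge$classes$genotype == "B/B", ]
  expect_lt(abs(het$solution - a_true), 2 * het$se)
  expect_lt(abs(hom$solution - 2 * a_true), 2 * hom$se)
  expect_lt(ge$wald_p, 0.01)
  # class counts echo the input exactly
  ids <- as.character(ph$fid)
  expect_equal(ge$classes$count,
               unname(as.integer(table(gv[ids])[c("0", "1", "2")])))
  # single-class input errors
  expect_error(genotype_effect(ph, stats::setNames(
    rep(1L, nrow(sim$genotypes)), rownames(sim$genotypes)), A),
    "fewer than two")
})

test_that("haplotype effects recode the focal haplotype against all others", {
  sim <- sim_fixture("base")
  ph <- acc_pheno(sim)
  A <- pedigree_amatrix(sim$pedigree)
  wsnps <- sim$map$snp[sim$map$chr == 3][17:21]
  ht <- extract_haplotypes(sim$truth$haplo_pat, sim$truth$haplo_mat, wsnps)
  focal <- ht$haplotypes$haplotype[1]
  he <- haplotype_effect(ph, ht, focal, A, fixed = "sex")
  # non-carriers form the baseline class; focal homozygotes land in B/B
  hom_ids <- ht$diplotypes$id[ht$diplotypes$hap1 == focal &
                                ht$diplotypes$hap2 == focal]
  non_ids <- ht$diplotypes$id[ht$diplotypes$hap1 != focal &
                                ht$diplotypes$hap2 != focal]
  ids <- as.character(ph$fid)
  if (length(hom_ids)) {
    expect_equal(he$classes$count[he$classes$genotype == "B/B"],
                 sum(ids %in% hom_ids))
  }
  expect_equal(he$classes$count[he$classes$genotype == "A/A"],
               sum(ids %in% non_ids))
  # absent and too-rare focal haplotypes error
  expect_error(haplotype_effect(ph, ht, "ZZZZZ", A), "absent")
  rare <- ht$haplotypes$haplotype[!ht$haplotypes$testable][1]
  if (!is.na(rare)) {
    expect_error(haplotype_effect(ph, ht, rare, A), "too few")
  }
})

test_that("allelic r2 behaves as a squared correlation", {
  sim <- sim_fixture("base")
  g <- sim$genotypes[, 1:6]
  r2 <- ld_r2(g)
  expect_equal(unname(diag(r2)), rep(1, 6))
  # strand flip leaves r2 unchanged
  gf <- cbind(g, flip = 2L - g[, 1])
  r2f <- ld_r2(gf)
  expect_equal(r2f["flip", colnames(g)[2]], r2[1, 2], tolerance = 1e-12)
  expect_equal(r2f[1, "flip"], 1)
  # independent loci at n = 500: near-zero background LD
  set.seed(8)
  gi <- sapply(runif(30, 0.1, 0.5), function(pp) rbinom(500, 2, pp))
  colnames(gi) <- paste0("u", 1:30)
  r2b <- ld_r2(gi)
  expect_lt(mean(r2b[upper.tri(r2b)], na.rm = TRUE), 0.01)
  # a haplotype defined by a single SNP reproduces that SNP's r2
  hap_dosage <- g[, 3]
  r2h <- ld_r2(cbind(g[, c(1, 3)], hap = hap_dosage))
  expect_equal(r2h["hap", 1], r2h[2, 1], tolerance = 1e-12)
  # monomorphic locus gets NA
  gm <- cbind(g[, 1:2], mono = rep(1L, nrow(g)))
  r2m <- ld_r2(gm)
  expect_true(all(is.na(r2m["mono", ])))
  expect_error(ld_r2(g[, 1, drop = FALSE]), "two loci")
})
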