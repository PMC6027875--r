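# a tiny synthetic map: one chromosome, SNPs at given cM positions
toy_map <- function(pos, chr = 1L) {
  data.frame(chr = chr, snp = sprintf("s%d_%d", chr, seq_along(pos)),
             cM = pos, bp = round(pos * 1e6) + 1L, stringsAsFactors = FALSE)
}

test_that("sub-pedigree construction requires all five members genotyped", {
  ped <- data.frame(
    id   = c("gs", "gd", "fid", "mate", "off1", "off2"),
    sire = c(NA, NA, "gs", NA, "fid", "fid"),
    dam  = c(NA, NA, "gd", NA, "mate", "mate"),
    sex  = c("M", "F", "M", "F", "F", "M"),
    stringsAsFactors = FALSE
  )
  subs <- build_subpedigrees(ped, ped$id)
  # fid is eligible for both offspring; mate has ungenotyped parents so is
  # never an FID herself
  expect_equal(nrow(subs), 2)
  expect_equal(subs$fid, c("fid", "fid"))
  expect_equal(subs$offspring, c("off1", "off2"))
  # dropping the maternal grandsire removes all pairs
  subs2 <- build_subpedigrees(ped, setdiff(ped$id, "gs"))
  expect_equal(nrow(subs2), 0)
  # empty genotype set
  expect_equal(nrow(build_subpedigrees(ped, character())), 0)
})

test_that("the Mendelian screen masks incompatibilities and discards bad pairs", {
  m <- 2000
  g5 <- matrix(1L, 5, m) # all heterozygous: never incompatible
  rownames(g5) <- c("fid", "mate", "sire", "dam", "off")
  # one opposite-homozygote conflict between sire and fid
  g5[3, 1] <- 0L; g5[1, 1] <- 2L
  scr <- screen_mendelian(g5, threshold = 0.001)
  expect_false(scr$discard) # 1/2000 = 0.0005 <= 0.001
  expect_true(is.na(scr$geno[3, 1]) && is.na(scr$geno[1, 1]))
  expect_false(is.na(scr$geno[2, 1])) # other members untouched

  # 3 mismatches in 1000 loci -> fraction 0.003 > 0.001 -> discard
  g5b <- matrix(1L, 5, 1000)
  g5b[1, 1:3] <- 0L
  g5b[5, 1:3] <- 2L
  expect_true(screen_mendelian(g5b)$discard)

  # error-free simulated data: no discards anywhere
  sim <- sim_fixture("base")
  cs <- call_acc(sim$genotypes, sim$pedigree, sim$map)
  expect_equal(sum(cs$records$mendel_discard), 0)
})

test_that("gamete phasing follows the informativeness rules", {
  map1 <- toy_map(c(10, 20))
  # rows fid, mate, sire, dam, off; dosages of allele B
  # SNP1: fid A/B, off A/A -> transmitted A; sire B/B cannot give A -> DAM
  # SNP2: fid A/B, off A/B, mate A/B -> indeterminate
  g5 <- rbind(fid = c(1L, 1L), mate = c(1L, 1L), sire = c(2L, 0L),
              dam = c(0L, 0L), off = c(0L, 1L))
  pv <- phase_gamete(g5, map1)
  expect_equal(pv[[1]], c(2L, NA))

  # heterozygous offspring resolved by a homozygous mate
  # off A/B, mate A/A -> FID gave B; dam lacks B -> SIRE
  g5b <- rbind(fid = 1L, mate = 0L, sire = 1L, dam = 0L, off = 1L)
  pvb <- phase_gamete(g5b, toy_map(5))
  expect_equal(pvb[[1]], 1L)

  # both parents could give the allele -> unknown
  g5c <- rbind(fid = 1L, mate = 0L, sire = 1L, dam = 1L, off = 1L)
  expect_true(is.na(phase_gamete(g5c, toy_map(5))[[1]]))

  # simulated error-free gametes: calls equal truth at every informative SNP
  sim <- sim_fixture("base")
  subs <- build_subpedigrees(sim$pedigree, rownames(sim$genotypes))
  for (i in seq_len(10)) {
    s <- subs[i, ]
    g5s <- sim$genotypes[c(s$fid, s$mate, s$sire, s$dam, s$offspring), ]
    called <- unlist(phase_gamete(g5s, sim$map))
    truth <- unlist(true_phase_vectors(sim, s$fid, s$offspring))
    inf <- !is.na(called)
    expect_gt(sum(inf), 0)
    expect_equal(called[inf], truth[inf])
  }
})

test_that("crossover calling applies the QC pipeline in order", {
  map5 <- toy_map(c(0, 5, 10, 15, 20))
  # S,S,S,D,D -> one crossover
  cc <- call_crossovers(list(c(1L, 1L, 1L, 2L, 2L)), map5)
  expect_equal(cc$acc, 1)
  expect_equal(cc$intervals$left_snp, "s1_3")
  expect_equal(cc$intervals$right_snp, "s1_4")

  # singleton run is masked: S,S,D,S,S -> 0
  cc2 <- call_crossovers(list(c(1L, 1L, 2L, 1L, 1L)), map5)
  expect_equal(cc2$acc, 0)
  expect_equal(cc2$n_singletons_masked, 1)

  # short double crossover: spans measured between flanking markers
  map6a <- toy_map(c(0, 4, 5, 7, 12, 20)) # internal D-run flanked 4 -> 12: 8 cM
  cc3 <- call_crossovers(list(c(1L, 1L, 2L, 2L, 1L, 1L)), map6a)
  expect_equal(cc3$acc, 0)
  expect_equal(cc3$n_short_doubles_masked, 1)
  map6b <- toy_map(c(0, 4, 6, 14, 16, 20)) # flanking span 4 -> 16: 12 cM
  cc4 <- call_crossovers(list(c(1L, 1L, 2L, 2L, 1L, 1L)), map6b)
  expect_equal(cc4$acc, 2)
  expect_equal(cc4$n_short_doubles_masked, 0)

  # a run at the chromosome end is never a double crossover
  cc5 <- call_crossovers(list(c(1L, 1L, 1L, 1L, 2L, 2L)), map6b)
  expect_equal(cc5$acc, 1)

  # raw count above the cap discards the gamete
  alt <- rep(c(1L, 2L), length.out = 80)
  mapl <- toy_map(seq(0, 79) * 1.0)
  cc6 <- call_crossovers(list(alt[1:80]), mapl, max_acc = 60)
  expect_true(cc6$high_count_discard)
  expect_true(is.na(cc6$acc))
})

test_that("masking never raises a count and calls are order-reversible", {
  sim <- sim_fixture("noisy")
  cs <- call_acc(sim$genotypes, sim$pedigree, sim$map)
  ok <- cs$records[!cs$records$mendel_discard & !cs$records$high_count_discard, ]
  expect_true(all(ok$acc <= ok$raw_acc))

  # reversing within-chromosome SNP order leaves ACC unchanged
  subs <- build_subpedigrees(sim$pedigree, rownames(sim$genotypes))
  s <- subs[3, ]
  scr <- screen_mendelian(sim$genotypes[c(s$fid, s$mate, s$sire, s$dam,
                                          s$offspring), ])
  pv <- phase_gamete(scr$geno, sim$map)
  fwd <- call_crossovers(pv, sim$map)
  L <- sim$config$chr_length_cM
  rev_map <- do.call(rbind, lapply(split(sim$map, sim$map$chr), function(mm) {
    mm <- mm[rev(seq_len(nrow(mm))), ]
    mm$cM <- L - mm$cM
    mm$bp <- as.integer(round(mm$cM * 1e6)) + 1L
    mm
  }))
  pv_rev <- lapply(pv, rev)
  bwd <- call_crossovers(pv_rev, rev_map)
  expect_equal(bwd$acc, fwd$acc)
  expect_equal(bwd$counts, fwd$counts)
})

test_that("phenotype summaries and the trans response are consistent", {
  sim <- sim_fixture("base")
  cs <- call_acc(sim$genotypes, sim$pedigree, sim$map)
  s <- summarize_acc(cs)
  ph <- s$pheno
  counts <- attr(ph, "counts")
  expect_equal(ph$acc, unname(rowSums(counts)))
  both <- s$summary[s$summary$group == "Both", ]
  expect_equal(both$n_xovers, sum(ph$acc))
  expect_equal(both$NFID, length(unique(ph$fid)))
  # one FID with several records still counts once
  one <- ph[ph$fid == ph$fid[1], ]
  expect_gt(nrow(one), 1)
  # trans response subtracts the focal chromosome
  tr <- trans_acc(ph, 1)
  expect_equal(tr, ph$acc - counts[, "1"])
  # hand-built record: counts (2,1,0) -> acc 3, trans chr1 = 1
  expect_equal(sum(c(2, 1, 0)) - 2, 1)
})
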