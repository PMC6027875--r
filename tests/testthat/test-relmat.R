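test_that("allele frequencies and the inbreeding coefficient follow the formula", {
  g <- rbind(a = c(0L, 2L, 1L), b = c(1L, 1L, 1L), c = c(2L, 0L, 1L))
  colnames(g) <- c("s1", "s2", "s3")
  fq <- allele_freqs(g)
  expect_equal(unname(fq$p), c(0.5, 0.5, 0.5))
  # an all-heterozygous individual at p = 0.5: per-SNP term
  # (1 - 2 + 0.5) / 0.5 = -1 at every SNP
  expect_equal(unname(fq$fhat3["b"]), -1)

  # simulated outbred founders: mean inbreeding within 3 SE of zero
  set.seed(31)
  p <- runif(2000, 0.1, 0.5)
  founders <- sapply(p, function(pp) rbinom(500, 2, pp))
  colnames(founders) <- paste0("m", seq_along(p))
  rownames(founders) <- paste0("f", 1:500)
  f3 <- allele_freqs(founders)$fhat3
  expect_lt(abs(mean(f3)), 3 * sd(f3) / sqrt(length(f3)))
})

test_that("the GRM matches a brute-force double loop and its diagonal contract", {
  g <- rbind(i1 = c(0L, 1L, 2L, 1L), i2 = c(1L, 1L, 0L, 2L),
             i3 = c(2L, 0L, 1L, 0L))
  colnames(g) <- paste0("s", 1:4)
  fq <- allele_freqs(g)
  A <- grm(g, fq, ridge = 0)
  # independent O(n^2 m) oracle
  p <- fq$p
  m <- 4L
  off <- function(j, k) {
    mean((g[j, ] - 2 * p) * (g[k, ] - 2 * p) / (2 * p * (1 - p)))
  }
  dia <- function(j) {
    1 + mean((g[j, ]^2 - (1 + 2 * p) * g[j, ] + 2 * p^2) / (2 * p * (1 - p)))
  }
  shift <- attr(A, "pd_shift")
  for (j in 1:3) {
    expect_equal(A[j, j] - shift, dia(j), tolerance = 1e-12)
    for (k in 1:3) if (j != k) expect_equal(A[j, k], off(j, k), tolerance = 1e-12)
  }
  # diag(GRM) - 1 equals the inbreeding coefficient exactly (same formula)
  expect_equal(unname(diag(A) - shift - 1), unname(fq$fhat3), tolerance = 1e-12)

  # duplicated individual: off-diagonal equals the original's (plain
  # cross-product) diagonal, the genotype columns being identical
  g2 <- rbind(g, i1copy = g["i1", ])
  A2 <- grm(g2, ridge = 0, adjust = FALSE)
  shift2 <- attr(A2, "pd_shift")
  expect_equal(A2["i1", "i1copy"], A2["i1", "i1"] - shift2, tolerance = 1e-12)
})

test_that("GRM off-diagonals of simulated parent-offspring pairs are near 0.5", {
  sim <- sim_fixture("base")
  A <- grm_cached(sim, "base")
  ped <- sim$pedigree
  nf <- ped[!is.na(ped$sire), ]
  po <- vapply(seq_len(nrow(nf)), function(i) A[nf$id[i], nf$sire[i]], 0)
  se <- sd(po) / sqrt(length(po))
  expect_lt(abs(mean(po) - 0.5), 3 * se)
  # founders are close to unrelated on average
  f <- ped$id[is.na(ped$sire)]
  Af <- A[f, f]
  offd <- Af[upper.tri(Af)]
  expect_lt(abs(mean(offd)), 3 * sd(offd) / sqrt(length(offd)) + 0.02)
})

test_that("subset and complement GRMs average back to the all-SNP GRM", {
  sim <- sim_fixture("base")
  g <- sim$genotypes
  fq <- allele_freqs(g)
  snps <- colnames(g)[fq$polymorphic]
  s1 <- snps[1:100]
  s2 <- setdiff(snps, s1)
  strip <- function(A) {
    diag(A) <- diag(A) - attr(A, "pd_shift") - attr(A, "ridge")
    A
  }
  A_all <- strip(grm(g, fq))
  A1 <- strip(suppressWarnings(grm(g, fq, snps = s1)))
  A2 <- strip(suppressWarnings(grm(g, fq, snps = s2)))
  m1 <- length(s1); m2 <- length(s2)
  expect_equal((m1 * A1 + m2 * A2) / (m1 + m2), A_all, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the pedigree relationship matrix gives textbook coefficients", {
  ped <- data.frame(
    id   = c("s", "d", "k1", "k2", "gk"),
    sire = c(NA, NA, "s", "s", "k1"),
    dam  = c(NA, NA, "d", "d", "d2"),
    sex  = c("M", "F", "M", "F", "M"), stringsAsFactors = FALSE
  )
  ped <- rbind(ped, data.frame(id = "d2", sire = NA, dam = NA, sex = "F"))
  A <- pedigree_amatrix(ped)
  expect_equal(A["s", "k1"], 0.5)   # parent-offspring
  expect_equal(A["k1", "k2"], 0.5)  # full sibs
  expect_equal(A["s", "s"], 1.0)    # non-inbred founder
  expect_equal(A["gk", "k2"], 0.25) # half relationship via k1
  expect_true(all(A >= 0 & A <= 2))
  # offspring of full sibs is inbred: diagonal above 1
  ped2 <- rbind(ped, data.frame(id = "inb", sire = "k1", dam = "k2",
                                sex = "F"))
  A2 <- pedigree_amatrix(ped2)
  expect_equal(A2["inb", "inb"], 1.25)
  # a pedigree cycle errors
  bad <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), sex = c("M", "M"))
  expect_error(pedigree_amatrix(bad), "cycle")
})

test_that("GCTA-style text GRMs round-trip", {
  sim <- sim_fixture("base")
  A <- grm_cached(sim, "base")
  pre <- file.path(withr::local_tempdir(), "t")
  write_grm(A, pre)
  A2 <- read_grm(pre)
  expect_equal(unname(A2), unname(as.matrix(A)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(A2), rownames(A))
  expect_equal(attr(A2, "m"), attr(A, "m"))
})
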