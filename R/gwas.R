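## median of a 1-df chi-square, the genomic-control null expectation
.CHI2_MEDIAN_1DF <- stats::qchisq(0.5, df = 1)

#' Genomic-control correction of association statistics
#'
#' \eqn{\lambda} is the observed median chi-square divided by the null
#' median of \eqn{\chi^2_1} (0.4549364). Statistics are divided by
#' \eqn{\lambda} only when \eqn{\lambda > 1}; deflation is never applied,
#' but \eqn{\lambda} is always reported.
#'
#' @param chi2 vector of 1-df association chi-squares.
#' @return list \code{lambda}, \code{chi2} (corrected), \code{p} (corrected
#'   p-values).
#' @export
genomic_control <- function(chi2) {
  ok <- is.finite(chi2)
  if (!any(ok)) stop("genomic_control(): no finite statistics")
  lambda <- stats::median(chi2[ok]) / .CHI2_MEDIAN_1DF
  adj <- if (lambda > 1) chi2 / lambda else chi2
  list(lambda = lambda, chi2 = adj,
       p = stats::pchisq(adj, 1, lower.tail = FALSE))
}

#' Repeated-measures mixed-model association scan
#'
#' Two-stage genome scan in the spirit of repeated-measures GWAS with a
#' kinship random effect: the null animal model (additive GRM +
#' permanent-environment + residual, with the configured fixed effects) is
#' fitted once by REML, its covariance is frozen, and each SNP's
#' mean-imputed dosage is then tested as a single generalized-least-squares
#' fixed covariate (1-df chi-square). Statistics are genomic-control
#' corrected via [genomic_control()].
#'
#' @param pheno data frame of gamete records (id column + response +
#'   fixed-effect columns).
#' @param genotypes id x SNP dosage matrix.
#' @param K genomic relatedness matrix.
#' @param map linkage map (rows matching the genotype columns); SNPs of
#'   unknown position may carry chromosome code 0/NA and are still scanned.
#' @param response,id,fixed model configuration as in
#'   [acc_animal_model()].
#' @param gc apply genomic control (default TRUE).
#' @param null_fit optionally, a pre-fitted null \code{varfit} to reuse.
#' @return data frame of class \code{acc_scan}: per SNP chromosome,
#'   position, alleles, MAF, effect of the B allele with SE, chi2, p and
#'   gc-corrected p; \code{lambda} and the null fit are attached as
#'   attributes. Monomorphic SNPs are skipped.
#' @export
snp_scan <- function(pheno, genotypes, K, map = NULL, response = "acc",
                     id = "fid", fixed = c("sex", "fiii"), gc = TRUE,
                     null_fit = NULL) {
  if (is.null(null_fit)) {
    null_fit <- acc_animal_model(pheno, K, response = response,
                                 fixed = fixed, id = id)
    if (!null_fit$converged) stop("snp_scan(): null model did not converge")
  }
  st <- null_fit$internals$st
  ev <- null_fit$internals$ev
  ids <- as.character(pheno[[id]])
  lev <- st$blocks[[1L]]$lev_names

  G <- genotypes[lev, , drop = FALSE]
  p_hat <- colMeans(G, na.rm = TRUE) / 2
  v_hat <- apply(G, 2L, stats::var, na.rm = TRUE)
  keep <- is.finite(p_hat) & p_hat > 0 & p_hat < 1 &
    is.finite(v_hat) & v_hat > 0
  G <- G[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0L)) G[is.na(G[, j]), j] <- 2 * p_hat[j]
  }

  # record-level dosage is Z g, so quadratic forms reduce to level space
  idx <- st$offs[1L] + seq_len(st$blocks[[1L]]$q)
  ZtPy <- ev$ZtPy[idx]
  ZtPZ <- ev$ZtPZ[idx, idx]
  num <- drop(crossprod(G, ZtPy))
  den <- colSums(G * (ZtPZ %*% G))
  effect <- num / den
  se <- 1 / sqrt(den)
  chi2 <- num^2 / den

  maf <- pmin(p_hat, 1 - p_hat)
  res <- data.frame(
    snp = colnames(G),
    chr = if (!is.null(map)) map$chr[match(colnames(G), map$snp)] else NA,
    cM = if (!is.null(map)) map$cM[match(colnames(G), map$snp)] else NA,
    allele_A = if (!is.null(map) && "allele_A" %in% names(map))
      map$allele_A[match(colnames(G), map$snp)] else NA,
    allele_B = if (!is.null(map) && "allele_B" %in% names(map))
      map$allele_B[match(colnames(G), map$snp)] else NA,
    maf = as.numeric(maf),
    effect_B = as.numeric(effect), se = as.numeric(se),
    chi2 = as.numeric(chi2),
    p = stats::pchisq(chi2, 1, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  if (gc) {
    gcres <- genomic_control(res$chi2)
    res$chi2_gc <- gcres$chi2
    res$p_gc <- gcres$p
    attr(res, "lambda") <- gcres$lambda
  }
  attr(res, "null_fit") <- null_fit
  class(res) <- c("acc_scan", "data.frame")
  res
}

#' LD-based effective number of tests and significance threshold
#'
#' SNPs are processed per chromosome in map order in blocks of
#' \code{window}; each block contributes an effective test count from its
#' pairwise allelic correlation (r-squared) matrix by the
#' Moskvina-Schmidt-type reduction
#' \eqn{K_{eff} = 1 + \sum_{i>1} \sqrt{1 - \max_{j<i} r^2_{ij}}}.
#' SNPs of unknown position (chromosome 0/NA) and monomorphic SNPs are
#' excluded. The genome-wide threshold is \eqn{\alpha / K_{eff}}.
#'
#' @param genotypes id x SNP dosage matrix.
#' @param map linkage map giving chromosome and order; NULL treats all SNPs
#'   as one chromosome in column order.
#' @param window block size in SNPs (default 50).
#' @param alpha genome-wide error rate (default 0.05).
#' @param k_eff optionally skip the computation and just do the threshold
#'   arithmetic for a known effective test count.
#' @return list \code{k_eff, alpha, threshold_p, window, n_snps}.
#' @export
keff_threshold <- function(genotypes = NULL, map = NULL, window = 50L,
                           alpha = 0.05, k_eff = NULL) {
  if (!is.null(k_eff)) {
    return(list(k_eff = k_eff, alpha = alpha, threshold_p = alpha / k_eff,
                window = window, n_snps = NA_integer_))
  }
  stopifnot(window >= 2L)
  p_hat <- colMeans(genotypes, na.rm = TRUE) / 2
  v_hat <- apply(genotypes, 2L, stats::var, na.rm = TRUE)
  poly <- is.finite(p_hat) & p_hat > 0 & p_hat < 1 &
    is.finite(v_hat) & v_hat > 0
  if (!any(poly)) stop("keff_threshold(): all SNPs monomorphic")
  snps <- colnames(genotypes)[poly]
  if (!is.null(map)) {
    chr <- map$chr[match(snps, map$snp)]
    ord <- order(chr, map$cM[match(snps, map$snp)])
    snps <- snps[ord]
    chr <- chr[ord]
    known <- !is.na(chr) & chr != 0
    snps <- snps[known]
    chr <- chr[known]
  } else {
    chr <- rep(1L, length(snps))
  }
  total <- 0
  for (cc in unique(chr)) {
    s <- snps[chr == cc]
    starts <- seq(1L, length(s), by = window)
    for (st0 in starts) {
      blk <- s[st0:min(st0 + window - 1L, length(s))]
      if (length(blk) == 1L) {
        total <- total + 1
        next
      }
      r2 <- stats::cor(genotypes[, blk, drop = FALSE],
                       use = "pairwise.complete.obs")^2
      kap <- c(1, vapply(2:length(blk), function(i) {
        sqrt(max(0, 1 - max(r2[i, seq_len(i - 1L)], na.rm = TRUE)))
      }, 0))
      total <- total + sum(kap)
    }
  }
  list(k_eff = total, alpha = alpha, threshold_p = alpha / total,
       window = window, n_snps = length(snps))
}

#' Association scan of trans crossover counts
#'
#' For each chromosome the response is ACC minus the crossovers called on
#' that chromosome, so SNPs can only associate through genome-wide (trans)
#' effects on rate. The null model is refitted per chromosome and SNPs on
#' that chromosome are tested against its trans response; results are
#' concatenated.
#'
#' @param pheno phenotype table carrying a \code{counts} attribute
#'   (gametes x chromosomes), as produced by [summarize_acc()].
#' @param genotypes,K,map,id,fixed,gc as in [snp_scan()].
#' @return an \code{acc_scan} data frame (all chromosomes combined); the
#'   genomic-control correction is applied to the pooled statistics.
#' @export
trans_scan <- function(pheno, genotypes, K, map, id = "fid",
                       fixed = c("sex", "fiii"), gc = TRUE) {
  counts <- attr(pheno, "counts")
  if (is.null(counts)) stop("trans_scan(): phenotype lacks per-chromosome counts")
  chrs <- sort(unique(map$chr[map$chr != 0 & !is.na(map$chr)]))
  if (length(chrs) == 1L) {
    warning("single-chromosome genome: trans response is identically zero; nothing tested")
    return(NULL)
  }
  pieces <- list()
  for (cc in chrs) {
    snps_c <- map$snp[map$chr == cc]
    snps_c <- intersect(snps_c, colnames(genotypes))
    if (!length(snps_c)) next
    ph <- pheno
    ph$acc_trans <- pheno$acc - counts[, as.character(cc)]
    sc <- snp_scan(ph, genotypes[, snps_c, drop = FALSE], K, map,
                   response = "acc_trans", id = id, fixed = fixed, gc = FALSE)
    attributes(sc)[c("lambda", "null_fit")] <- NULL
    class(sc) <- "data.frame"
    pieces[[length(pieces) + 1L]] <- sc
  }
  res <- do.call(rbind, pieces)
  if (gc && nrow(res)) {
    gcres <- genomic_control(res$chi2)
    res$chi2_gc <- gcres$chi2
    res$p_gc <- gcres$p
    attr(res, "lambda") <- gcres$lambda
  }
  class(res) <- c("acc_scan", "data.frame")
  res
}
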