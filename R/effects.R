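#' Effect of a SNP genotype on ACC, fitted as a fixed factor
#'
#' Animal model with the genotype class (A/A, A/B, B/B) as a fixed factor
#' and a relatedness random effect absorbing the remaining additive genetic
#' variance, plus permanent-environment and residual terms. The baseline
#' class is the homozygote of the alphabetically first allele; solutions of
#' the other classes are deviations from it. Classes with no records are
#' dropped; classes with fewer than 10 records are flagged as subject to
#' large sampling error.
#'
#' @param pheno gamete-record phenotype table.
#' @param genotype_vector named per-individual dosage (0/1/2) of the B
#'   allele, or a character vector of class labels.
#' @param K relatedness matrix (pedigree numerator or genomic).
#' @param labels class labels for dosages 0, 1, 2 (default
#'   \code{c("A/A", "A/B", "B/B")}).
#' @param response,id,fixed model configuration; \code{fixed} covariates are
#'   added after the genotype factor.
#' @return list of class \code{genofit}: \code{classes} (per class: count,
#'   unique-individual count, solution, SE, z, rare flag), \code{wald_p}
#'   (joint test of the genotype factor), \code{fit}.
#' @export
genotype_effect <- function(pheno, genotype_vector, K,
                            labels = c("A/A", "A/B", "B/B"),
                            response = "acc", id = "fid", fixed = NULL) {
  ids <- as.character(pheno[[id]])
  g <- genotype_vector[ids]
  cls <- if (is.numeric(g)) labels[g + 1L] else as.character(g)
  keep <- !is.na(cls)
  if (!all(keep)) {
    pheno <- pheno[keep, , drop = FALSE]
    ids <- ids[keep]
    cls <- cls[keep]
  }
  present <- intersect(labels, unique(cls))
  if (length(present) < 2L) {
    stop("genotype_effect(): fewer than two genotype classes present")
  }
  f <- factor(cls, levels = present)
  df <- cbind(data.frame(.genoclass = f), pheno)
  fixed <- if (is.null(fixed)) character() else fixed[fixed %in% names(pheno)]
  X <- stats::model.matrix(stats::reformulate(c(".genoclass", fixed)), df)
  colnames(X)[1L] <- paste0(present[1L], " (Intercept)")
  gcols <- seq_len(length(present) - 1L) + 1L
  colnames(X)[gcols] <- present[-1L]
  fit <- reml_fit(pheno[[response]], X, random = list(
    u = list(levels = ids, K = list(a = K[sort(unique(ids)), sort(unique(ids))],
                                    pe = NULL), positive = c(TRUE, TRUE))
  ))
  w <- wald_fixed(fit, present[-1L])
  counts <- table(f)
  idcounts <- vapply(present, function(cl) length(unique(ids[cls == cl])), 1L)
  bi <- match(c(paste0(present[1L], " (Intercept)"), present[-1L]),
              fit$beta$term)
  classes <- data.frame(
    genotype = present,
    count = as.integer(counts[present]),
    id_count = as.integer(idcounts),
    solution = fit$beta$estimate[bi],
    se = fit$beta$se[bi],
    z = fit$beta$z[bi],
    rare = as.integer(counts[present]) < 10L,
    stringsAsFactors = FALSE
  )
  structure(list(classes = classes, wald_p = w$p, wald_chi2 = w$statistic,
                 wald_df = w$df, fit = fit),
            class = "genofit")
}

#' @export
print.genofit <- function(x, ...) {
  print(x$classes, row.names = FALSE)
  cat(sprintf("Joint Wald test: chi2 = %.3f (df %d), P = %.3g\n",
              x$wald_chi2, x$wald_df, x$wald_p))
  invisible(x)
}

#' Tabulate haplotypes over a SNP window from phased genotypes
#'
#' Builds the two allele strings each individual carries across a window
#' and counts copies of every distinct haplotype, both in total and in
#' unique carriers. Haplotypes with more than \code{min_copies} copies are
#' flagged testable. Individuals with a missing/unphased site in the window
#' are excluded.
#'
#' @param haplo1,haplo2 id x SNP matrices of phased alleles (0/1 dosage or
#'   letters), e.g. the simulator's truth haplotypes or trio-resolved phase.
#' @param window_snps character vector of SNP columns forming the window,
#'   in map order.
#' @param min_copies testability threshold: strictly more than this many
#'   copies (default 10).
#' @return list of class \code{haplo_table}: \code{haplotypes} (string,
#'   copies, carriers, testable), \code{diplotypes} (per individual: hap1,
#'   hap2), \code{n_excluded}.
#' @export
extract_haplotypes <- function(haplo1, haplo2, window_snps, min_copies = 10L) {
  h1 <- haplo1[, window_snps, drop = FALSE]
  h2 <- haplo2[, window_snps, drop = FALSE]
  ok <- !(rowSums(is.na(h1)) > 0L | rowSums(is.na(h2)) > 0L)
  n_excl <- sum(!ok)
  h1 <- h1[ok, , drop = FALSE]
  h2 <- h2[ok, , drop = FALSE]
  s1 <- apply(h1, 1L, paste, collapse = "")
  s2 <- apply(h2, 1L, paste, collapse = "")
  copies <- table(c(s1, s2))
  carriers <- vapply(names(copies), function(h) {
    sum(s1 == h | s2 == h)
  }, 1L)
  haps <- data.frame(
    haplotype = names(copies),
    copies = as.integer(copies),
    carriers = as.integer(carriers),
    testable = as.integer(copies) > min_copies,
    stringsAsFactors = FALSE
  )
  haps <- haps[order(-haps$copies), , drop = FALSE]
  rownames(haps) <- NULL
  structure(list(
    haplotypes = haps,
    diplotypes = data.frame(id = rownames(h1), hap1 = s1, hap2 = s2,
                            stringsAsFactors = FALSE, row.names = NULL),
    n_excluded = n_excl
  ), class = "haplo_table")
}

#' Effect of one haplotype versus all others combined
#'
#' Every haplotype other than the focal one is collapsed into a single
#' pseudo-allele, diplotypes are recoded to a three-class genotype factor by
#' focal-copy number (A/A = no copy, A/B = one, B/B = two), and the
#' genotype-as-fixed-factor animal model of [genotype_effect()] is fitted.
#' The baseline class is the common non-carrier diplotype, so the A/B
#' solution estimates the per-copy effect of the focal haplotype (its
#' homozygotes are typically rare and their estimate sampling-noisy).
#'
#' @param pheno gamete-record phenotype table.
#' @param haplotable a \code{haplo_table} from [extract_haplotypes()].
#' @param focal_haplotype the allele string to test (must be testable:
#'   more than the copy threshold).
#' @param K relatedness matrix.
#' @param ... passed to [genotype_effect()].
#' @return a \code{genofit}.
#' @export
haplotype_effect <- function(pheno, haplotable, focal_haplotype, K, ...) {
  hrow <- haplotable$haplotypes[
    haplotable$haplotypes$haplotype == focal_haplotype, ]
  if (nrow(hrow) == 0L) stop("focal haplotype absent from the table")
  if (!hrow$testable) {
    stop("focal haplotype has too few copies to be testable (",
         hrow$copies, ")")
  }
  dd <- haplotable$diplotypes
  dosage_focal <- (dd$hap1 == focal_haplotype) + (dd$hap2 == focal_haplotype)
  gvec <- stats::setNames(dosage_focal, dd$id) # copies of the focal haplotype
  genotype_effect(pheno, gvec, K, ...)
}

#' Pairwise linkage disequilibrium as allelic correlation r-squared
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' individuals. Haplotypes can be included as presence dosages (0/1/2
#' copies). Monomorphic loci get NA rows/columns.
#'
#' @param dosages id x locus matrix (SNP dosages and/or haplotype copy
#'   counts).
#' @return symmetric matrix of r-squared values.
#' @export
ld_r2 <- function(dosages) {
  if (ncol(dosages) < 2L) stop("ld_r2(): need at least two loci")
  v <- apply(dosages, 2L, stats::var, na.rm = TRUE)
  mono <- !is.finite(v) | v == 0
  # cor() warns on zero-variance columns; those become NA rows below
  r2 <- suppressWarnings(stats::cor(dosages, use = "pairwise.complete.obs"))^2
  r2[mono, ] <- NA_real_
  r2[, mono] <- NA_real_
  diag(r2)[!mono] <- 1
  r2
}
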