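#' Allele frequencies and genomic inbreeding coefficients
#'
#' Computes per-SNP reference (B) allele frequencies from mean dosage and
#' the variance-based genomic inbreeding coefficient for each individual,
#' \deqn{F_j = \frac{1}{m}\sum_i \frac{x_{ij}^2 - (1+2p_i)x_{ij} + 2p_i^2}
#'   {2p_i(1-p_i)},}
#' averaging over the polymorphic SNPs with a non-missing genotype.
#'
#' @param genotypes id x SNP dosage matrix (0/1/2, NA missing).
#' @return list with \code{p} (per-SNP frequency), \code{polymorphic}
#'   (logical; monomorphic or all-missing SNPs are flagged out), \code{fhat3}
#'   (named per-individual inbreeding coefficient).
#' @export
allele_freqs <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  all_missing <- !is.finite(p)
  poly <- !all_missing & p > 0 & p < 1
  if (any(all_missing)) {
    message(sum(all_missing), " SNP(s) with all genotypes missing excluded")
  }
  x <- genotypes[, poly, drop = FALSE]
  pp <- p[poly]
  denom <- 2 * pp * (1 - pp)
  # per-SNP term: (x^2 - (1+2p)x + 2p^2) / (2p(1-p))
  num <- x^2 - sweep(x, 2L, 1 + 2 * pp, "*") + rep(2 * pp^2, each = nrow(x))
  term <- sweep(num, 2L, denom, "/")
  fhat3 <- rowMeans(term, na.rm = TRUE)
  list(p = p, polymorphic = poly, fhat3 = fhat3)
}

#' Genomic relatedness matrix (GRM)
#'
#' Marker-based additive relatedness with the sampling-error-corrected
#' diagonal: off-diagonals are
#' \eqn{A_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))} and
#' the diagonal is \eqn{1 + F_j} with the inbreeding coefficient of
#' [allele_freqs()], which assumes genotyped and causal loci share a
#' frequency spectrum. Missing genotypes are mean-imputed to \eqn{2p_i}.
#' A small ridge keeps window-restricted matrices (rank at most the window
#' size) numerically positive definite for REML.
#'
#' @param genotypes id x SNP dosage matrix.
#' @param freqs optional result of [allele_freqs()] on the full panel, so
#'   SNP subsets reuse shared frequencies.
#' @param snps optional character/integer subset of SNPs to use.
#' @param exclude optional subset of SNPs to drop (applied after
#'   \code{snps}).
#' @param ridge value added to the diagonal (default 1e-8).
#' @param adjust use the sampling-error-corrected diagonal \eqn{1 + F_j}
#'   (default). \code{adjust = FALSE} keeps the plain cross-product
#'   diagonal, which is positive semidefinite by construction; the regional
#'   heritability models use it for small SNP windows, where the corrected
#'   diagonal is too noisy to factorize.
#' @return symmetric matrix with id dimnames; attributes \code{m} (SNPs
#'   used), \code{ridge} and \code{pd_shift}.
#' @export
grm <- function(genotypes, freqs = NULL, snps = NULL, exclude = NULL,
                ridge = 1e-8, adjust = TRUE) {
  if (is.null(freqs)) freqs <- allele_freqs(genotypes)
  keep <- colnames(genotypes)[freqs$polymorphic]
  if (!is.null(snps)) {
    if (is.numeric(snps)) snps <- colnames(genotypes)[snps]
    keep <- intersect(keep, snps)
  }
  if (!is.null(exclude)) {
    if (is.numeric(exclude)) exclude <- colnames(genotypes)[exclude]
    keep <- setdiff(keep, exclude)
  }
  m <- length(keep)
  if (m == 0L) stop("grm(): no polymorphic SNPs left")
  x <- genotypes[, keep, drop = FALSE]
  pp <- freqs$p[keep]
  # mean-impute missing to 2p
  if (anyNA(x)) {
    for (j in which(colSums(is.na(x)) > 0L)) {
      x[is.na(x[, j]), j] <- 2 * pp[j]
    }
  }
  w <- sweep(x, 2L, 2 * pp, "-")
  w <- sweep(w, 2L, sqrt(2 * pp * (1 - pp)), "/")
  A <- tcrossprod(w) / m
  if (adjust) {
    # corrected diagonal: 1 + F^III over the same SNP subset
    xs <- genotypes[, keep, drop = FALSE]
    num <- xs^2 - sweep(xs, 2L, 1 + 2 * pp, "*") + rep(2 * pp^2, each = nrow(xs))
    term <- sweep(num, 2L, 2 * pp * (1 - pp), "/")
    diag(A) <- 1 + rowMeans(term, na.rm = TRUE)
  }
  A <- (A + t(A)) / 2
  diag(A) <- diag(A) + ridge
  A <- ensure_pd(A, tol = ridge)
  attr(A, "m") <- m
  attr(A, "ridge") <- ridge
  A
}

#' Make a relatedness matrix numerically positive definite
#'
#' The sampling-error-corrected GRM diagonal can leave small negative
#' eigenvalues on finite SNP panels; REML needs the covariance factorizable.
#' If the smallest eigenvalue falls below \code{tol}, the deficit is added
#' to the whole diagonal (with a warning when it exceeds \code{warn_above}).
#'
#' @param A symmetric matrix.
#' @param tol target minimum eigenvalue (default 1e-8).
#' @param warn_above warn when the applied shift exceeds this (default
#'   0.25).
#' @return the (possibly shifted) matrix; the shift is recorded in
#'   attribute \code{pd_shift}.
#' @export
ensure_pd <- function(A, tol = 1e-8, warn_above = 0.25) {
  lmin <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  shift <- 0
  if (lmin < tol) {
    shift <- tol - lmin
    diag(A) <- diag(A) + shift
    if (shift > warn_above) {
      warning(sprintf(
        "relatedness matrix has smallest eigenvalue %.3g; diagonal shifted by %.3g",
        lmin, shift))
    }
  }
  attr(A, "pd_shift") <- shift
  A
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' \eqn{A_{ii} = 1 + \tfrac12 A_{sd}} and
#' \eqn{A_{ij} = \tfrac12 (A_{j,sire(i)} + A_{j,dam(i)})}, with unknown
#' parents contributing zero. Individuals are processed in topological
#' order; a pedigree cycle is an error.
#'
#' @param pedigree data frame with \code{id, sire, dam}.
#' @return symmetric matrix with id dimnames.
#' @export
pedigree_amatrix <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  si <- idx[pedigree$sire]
  di <- idx[pedigree$dam]
  # topological order: repeatedly emit individuals whose parents are placed
  placed <- is.na(si) & is.na(di)
  ord <- which(placed)
  while (length(ord) < n) {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) stop("pedigree_amatrix(): pedigree contains a cycle")
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    s <- si[i]; d <- di[i]
    prev <- ord[seq_len(match(i, ord) - 1L)]
    if (length(prev)) {
      rs <- if (!is.na(s)) A[s, prev] else 0
      rd <- if (!is.na(d)) A[d, prev] else 0
      A[i, prev] <- A[prev, i] <- 0.5 * (rs + rd)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Write a relatedness matrix in GCTA text format
#'
#' \code{PREFIX.grm.gz} holds the lower triangle as
#' \code{i j m A_ij} (1-based indices, SNP count m) and \code{PREFIX.grm.id}
#' the ids (family column fixed at 1).
#'
#' @param A relatedness matrix with id dimnames.
#' @param prefix output path prefix.
#' @param m SNP count to record (defaults to the matrix's \code{m}
#'   attribute, or 0).
#' @return invisibly, the two paths.
#' @export
write_grm <- function(A, prefix, m = NULL) {
  if (is.null(m)) m <- attr(A, "m")
  if (is.null(m)) m <- 0L
  n <- nrow(A)
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(
    data.frame(i, j, m, A[cbind(i, j)]),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  close(con)
  utils::write.table(data.frame(1L, rownames(A)), paste0(prefix, ".grm.id"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(c(paste0(prefix, ".grm.gz"), paste0(prefix, ".grm.id")))
}

#' Read a GCTA text-format relatedness matrix
#'
#' @param prefix path prefix (expects \code{PREFIX.grm.gz} and
#'   \code{PREFIX.grm.id}).
#' @return symmetric matrix with id dimnames and attribute \code{m}.
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2L]]
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(tri[[1L]], tri[[2L]])] <- tri[[4L]]
  A[cbind(tri[[2L]], tri[[1L]])] <- tri[[4L]]
  attr(A, "m") <- tri[[3L]][1L]
  A
}
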