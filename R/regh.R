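#' Sliding SNP windows over a linkage map
#'
#' Windows of \code{size} SNPs advance by \code{size - overlap} within each
#' chromosome. When trailing SNPs remain uncovered, a final truncated
#' window from the next start to the chromosome end is appended provided it
#' holds at least \code{size/2} SNPs. A chromosome with fewer than
#' \code{size} SNPs yields a single whole-chromosome window.
#'
#' @param map linkage map.
#' @param size window size in SNPs (default 20).
#' @param overlap SNPs shared by consecutive windows (default 10; fine-map
#'   scans use \code{size - 1}).
#' @return data frame \code{chr, start, stop, first_snp, last_snp, n_snps,
#'   span_bp} (start/stop are within-chromosome map-order indices).
#' @export
make_windows <- function(map, size = 20L, overlap = 10L) {
  stopifnot(overlap < size, size >= 2L)
  step <- size - overlap
  out <- list()
  for (cc in sort(unique(map$chr))) {
    sub <- map[map$chr == cc, , drop = FALSE]
    sub <- sub[order(sub$cM), , drop = FALSE]
    ns <- nrow(sub)
    if (ns < size) {
      if (ns >= 2L) {
        out[[length(out) + 1L]] <- data.frame(
          chr = cc, start = 1L, stop = ns, first_snp = sub$snp[1L],
          last_snp = sub$snp[ns], n_snps = ns,
          span_bp = sub$bp[ns] - sub$bp[1L], stringsAsFactors = FALSE
        )
      }
      next
    }
    starts <- seq(1L, ns - size + 1L, by = step)
    stops <- starts + size - 1L
    last_cov <- stops[length(stops)]
    if (last_cov < ns) {
      s2 <- starts[length(starts)] + step
      if (ns - s2 + 1L >= size / 2) {
        starts <- c(starts, s2)
        stops <- c(stops, ns)
      }
    }
    for (k in seq_along(starts)) {
      i <- starts[k]; j <- stops[k]
      out[[length(out) + 1L]] <- data.frame(
        chr = cc, start = i, stop = j, first_snp = sub$snp[i],
        last_snp = sub$snp[j], n_snps = j - i + 1L,
        span_bp = sub$bp[j] - sub$bp[i], stringsAsFactors = FALSE
      )
    }
  }
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  win
}

#' Fit the two-GRM regional heritability model for one window
#'
#' Partitions additive variance between a GRM built from the window's SNPs
#' and a GRM from all remaining autosomal SNPs, alongside the
#' permanent-environment and residual terms, and tests the window variance
#' by a 1-df likelihood-ratio comparison against the model without the
#' window term. Regional h2 is the window component divided by the sum of
#' all components.
#'
#' @param pheno gamete-record phenotype table.
#' @param window one row of [make_windows()] output.
#' @param genotypes,map full genotype matrix and map.
#' @param K_all optional precomputed all-SNP GRM built with
#'   \code{grm(genotypes, adjust = FALSE)} (the window decomposition needs
#'   the plain cross-product form), reused across windows for speed.
#' @param freqs optional [allele_freqs()] result.
#' @param response,id,fixed model configuration.
#' @return one-row data frame: window columns plus \code{v_window, v_rest,
#'   v_pe, v_resid, regional_h2, regional_h2_se, chi2, p, converged}.
#' @export
fit_window <- function(pheno, window, genotypes, map, K_all = NULL,
                       freqs = NULL, response = "acc", id = "fid",
                       fixed = c("sex", "fiii")) {
  if (is.null(freqs)) freqs <- allele_freqs(genotypes)
  sub <- map[map$chr == window$chr, , drop = FALSE]
  sub <- sub[order(sub$cM), , drop = FALSE]
  win_snps <- sub$snp[window$start:window$stop]
  win_snps <- intersect(win_snps, colnames(genotypes)[freqs$polymorphic])
  if (!length(win_snps)) stop("fit_window(): window has no polymorphic SNPs")

  K_win <- grm(genotypes, freqs = freqs, snps = win_snps, adjust = FALSE)
  if (is.null(K_all)) K_all <- grm(genotypes, freqs = freqs, adjust = FALSE)
  m_all <- attr(K_all, "m"); m_win <- attr(K_win, "m")
  m_rest <- m_all - m_win
  if (m_rest <= 0) stop("fit_window(): no rest-of-genome SNPs")
  # exact SNP-count-weighted decomposition of the all-SNP GRM
  K_rest <- (m_all * K_all - m_win * K_win) / m_rest
  K_rest <- ensure_pd(K_rest)
  attr(K_rest, "m") <- m_rest

  y <- pheno[[response]]
  ids <- as.character(pheno[[id]])
  fixed <- fixed[fixed %in% names(pheno)]
  X <- if (length(fixed)) {
    stats::model.matrix(stats::reformulate(fixed), data = pheno)
  } else NULL

  full <- reml_fit(y, X, random = list(
    u = list(levels = ids,
             K = list(win = K_win, rest = K_rest, pe = NULL),
             positive = c(TRUE, TRUE, TRUE))
  ))
  red <- reml_fit(y, X, random = list(
    u = list(levels = ids, K = list(rest = K_rest, pe = NULL),
             positive = c(TRUE, TRUE))
  ))
  test <- lrt(full, red)
  th <- full$theta
  ridx <- match("u.win", full$ratios$term)
  data.frame(
    window[, c("chr", "start", "stop", "first_snp", "last_snp", "n_snps")],
    v_window = th[["u.win"]], v_rest = th[["u.rest"]], v_pe = th[["u.pe"]],
    v_resid = th[["residual"]],
    v_window_se = full$components$se[match("u.win", full$components$term)],
    v_rest_se = full$components$se[match("u.rest", full$components$term)],
    regional_h2 = full$ratios$ratio[ridx],
    regional_h2_se = full$ratios$se[ridx],
    chi2 = test$chi2, p = if (full$converged && red$converged) test$p else NA,
    converged = full$converged && red$converged,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Genome-wide regional heritability scan
#'
#' Fits [fit_window()] for every sliding window and applies the
#' overlap-corrected Bonferroni threshold \eqn{\alpha / (n_{windows}/2)}.
#'
#' @param pheno,genotypes,map,response,id,fixed as in [fit_window()].
#' @param size,overlap window geometry (defaults 20 and 10).
#' @param alpha genome-wide error rate.
#' @return list \code{windows} (stacked [fit_window()] rows with a
#'   \code{significant} flag), \code{threshold_p}, \code{n_windows}.
#' @export
scan_regions <- function(pheno, genotypes, map, size = 20L, overlap = 10L,
                         alpha = 0.05, response = "acc", id = "fid",
                         fixed = c("sex", "fiii")) {
  if (is.null(pheno) || nrow(pheno) == 0L) stop("scan_regions(): empty phenotype")
  wins <- make_windows(map, size, overlap)
  freqs <- allele_freqs(genotypes)
  K_all <- grm(genotypes, freqs = freqs, adjust = FALSE)
  rows <- lapply(seq_len(nrow(wins)), function(k) {
    fit_window(pheno, wins[k, ], genotypes, map, K_all = K_all,
               freqs = freqs, response = response, id = id, fixed = fixed)
  })
  tab <- do.call(rbind, rows)
  thr <- alpha / (nrow(wins) / 2)
  tab$significant <- !is.na(tab$p) & tab$p < thr
  list(windows = tab, threshold_p = thr, n_windows = nrow(wins))
}

#' Fine-map a significant region with n-1-overlap windows
#'
#' Re-runs the regional heritability model over a significant window plus a
#' flanking margin, for several window sizes with windows advancing one SNP
#' at a time. Fine-map p-values are exploratory (the genome-wide Bonferroni
#' rule is defined for the primary scan only).
#'
#' @param pheno,genotypes,map,response,id,fixed as in [fit_window()].
#' @param region list or one-row data frame with \code{chr} and the bp range
#'   \code{from_bp, to_bp} (e.g. a significant scan window's span).
#' @param sizes window sizes to try (default 20, 10, 6).
#' @param margin_bp flank added on each side (default 5e6); clipped at the
#'   chromosome ends.
#' @return stacked [fit_window()] rows with a \code{size} column.
#' @export
finemap <- function(pheno, genotypes, map, region, sizes = c(20L, 10L, 6L),
                    margin_bp = 5e6, response = "acc", id = "fid",
                    fixed = c("sex", "fiii")) {
  sub <- map[map$chr == region$chr, , drop = FALSE]
  sub <- sub[order(sub$cM), , drop = FALSE]
  lo <- max(region$from_bp - margin_bp, min(sub$bp))
  hi <- min(region$to_bp + margin_bp, max(sub$bp))
  inreg <- which(sub$bp >= lo & sub$bp <= hi)
  if (length(inreg) < 2L) stop("finemap(): fewer than two SNPs in region")
  regmap <- sub[inreg, , drop = FALSE]
  freqs <- allele_freqs(genotypes)
  K_all <- grm(genotypes, freqs = freqs, adjust = FALSE)
  out <- list()
  for (s in sizes) {
    if (nrow(regmap) < s) next
    wins <- make_windows(regmap, size = s, overlap = s - 1L)
    for (k in seq_len(nrow(wins))) {
      # window indices are relative to the region; map back to chromosome
      w <- wins[k, ]
      w$start <- inreg[w$start]
      w$stop <- inreg[w$stop]
      row <- fit_window(pheno, w, genotypes, map, K_all = K_all,
                        freqs = freqs, response = response, id = id,
                        fixed = fixed)
      row$size <- s
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
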