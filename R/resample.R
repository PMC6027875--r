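#' Sex-balanced resampling of a statistic with a Welch comparison
#'
#' Tests whether a male/female difference in an estimate (heritability, SNP
#' association chi-square, window LRT, ...) is an artifact of unequal sample
#' size: \code{n} records are sampled with replacement within each sex, the
#' statistic is recomputed on each resampled set, and the per-sex replicate
#' means are compared with a Welch two-sample t-test (unequal variances,
#' Satterthwaite degrees of freedom). The sampling unit is the gamete
#' record (a measure); set \code{unit = "individual"} to resample focal
#' individuals with all their records instead.
#'
#' @param pheno gamete-record phenotype table with a sex column.
#' @param statistic function taking a resampled phenotype subset (one sex)
#'   and returning a numeric scalar; failures yield NA replicates that are
#'   excluded from the t-test.
#' @param n records drawn per replicate within each sex (default 482).
#' @param reps replicates (default 100).
#' @param seed integer seed; required.
#' @param sex_col name of the sex column.
#' @param unit resampling unit.
#' @return list of class \code{resample_result}: \code{female, male}
#'   (replicate vectors), \code{t, df, p} (Welch test), \code{n, reps},
#'   \code{statistic_label}.
#' @export
balanced_resample <- function(pheno, statistic, n = 482L, reps = 100L, seed,
                              sex_col = "sex", unit = c("record", "individual")) {
  if (missing(seed) || is.null(seed)) {
    stop("balanced_resample(): an explicit seed is required")
  }
  unit <- match.arg(unit)
  sexes <- c("F", "M")
  if (!all(sexes %in% pheno[[sex_col]])) {
    stop("balanced_resample(): both sexes must be present")
  }
  set.seed(seed)
  draws <- lapply(sexes, function(s) {
    sub <- pheno[pheno[[sex_col]] == s, , drop = FALSE]
    vapply(seq_len(reps), function(r) {
      if (unit == "record") {
        take <- sample.int(nrow(sub), n, replace = TRUE)
        samp <- sub[take, , drop = FALSE]
      } else {
        ids <- unique(sub$fid)
        take <- sample(ids, n, replace = TRUE)
        samp <- do.call(rbind, lapply(seq_along(take), function(k) {
          block <- sub[sub$fid == take[k], , drop = FALSE]
          block$fid <- paste0(block$fid, ".rep", k) # copies stay distinct
          block
        }))
      }
      tryCatch(as.numeric(statistic(samp)), error = function(e) NA_real_)
    }, 0)
  })
  names(draws) <- c("female", "male")
  fr <- draws$female[is.finite(draws$female)]
  mr <- draws$male[is.finite(draws$male)]
  tt <- stats::t.test(fr, mr, var.equal = FALSE)
  structure(list(
    female = draws$female, male = draws$male,
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_female = mean(fr), mean_male = mean(mr),
    n = n, reps = reps,
    n_failed = sum(!is.finite(c(draws$female, draws$male)))
  ), class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf(
    "Sex-balanced resampling (%d reps, n = %d): mean F = %.4f, mean M = %.4f\n",
    x$reps, x$n, x$mean_female, x$mean_male))
  cat(sprintf("Welch t = %.3f, df = %.1f, P = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Ready-made resampling statistics
#'
#' Helpers returning closures suitable for [balanced_resample()]:
#' \code{stat_h2} recomputes the additive proportion of variance from the
#' animal model, \code{stat_snp_chi2} the association chi-square of one SNP,
#' and \code{stat_window_chi2} the regional heritability LRT of one window.
#'
#' @param K relatedness matrix.
#' @param fixed fixed-effect columns (sex is omitted automatically inside a
#'   single-sex resample).
#' @param genotypes,map,snp,window for the SNP / window statistics.
#' @return a function of one argument (a phenotype subset).
#' @name resample_statistics
NULL

#' @rdname resample_statistics
#' @export
stat_h2 <- function(K, fixed = "fiii") {
  function(sub) {
    fit <- acc_animal_model(sub, K, fixed = fixed)
    fit$ratios$ratio[match("u.additive", fit$ratios$term)]
  }
}

#' @rdname resample_statistics
#' @export
stat_snp_chi2 <- function(genotypes, K, snp, fixed = "fiii") {
  g <- genotypes[, snp, drop = FALSE]
  function(sub) {
    sc <- snp_scan(sub, g, K, fixed = fixed, gc = FALSE)
    sc$chi2[1L]
  }
}

#' @rdname resample_statistics
#' @export
stat_window_chi2 <- function(genotypes, map, window, fixed = "fiii") {
  function(sub) {
    fit_window(sub, window, genotypes, map, fixed = fixed)$chi2
  }
}
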