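#' Fit the standard ACC animal model
#'
#' Convenience wrapper around [reml_fit()] for the repeated-measures animal
#' model of autosomal crossover count: additive genetic effect with a
#' relatedness matrix, permanent-environment effect of the focal individual
#' (always retained, as is the genomic inbreeding covariate when supplied),
#' and residual.
#'
#' @param pheno data frame with one row per gamete record; needs the id
#'   column and the response, plus any fixed-effect columns.
#' @param K relatedness matrix (genomic or pedigree) with id dimnames.
#' @param response,id column names for the response and the focal id.
#' @param fixed character vector of fixed-effect columns (factors expand to
#'   dummies; columns absent from \code{pheno} are ignored with a message).
#' @param pe include the permanent-environment term (default TRUE).
#' @param ... passed to [reml_fit()].
#' @return a \code{varfit}.
#' @export
acc_animal_model <- function(pheno, K, response = "acc", fixed = c("sex", "fiii"),
                             id = "fid", pe = TRUE, ...) {
  y <- pheno[[response]]
  ids <- as.character(pheno[[id]])
  fixed <- fixed[fixed %in% names(pheno)]
  X <- if (length(fixed)) {
    stats::model.matrix(stats::reformulate(fixed), data = pheno)
  } else {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  Ks <- list(additive = K)
  pos <- TRUE
  if (pe) {
    Ks["pe"] <- list(NULL) # identity covariance
    pos <- c(TRUE, TRUE)
  }
  reml_fit(y, X, random = list(u = list(levels = ids, K = Ks, positive = pos)),
           ...)
}

#' Variance proportions (heritability and friends)
#'
#' Each variance component divided by the sum of all components including
#' the residual. Accepts a fitted \code{varfit} (returning its ratio table)
#' or a named numeric vector of components.
#'
#' @param fit a \code{varfit}, or named numeric vector of variance
#'   components (residual included).
#' @return data frame \code{term, ratio, se} (SEs NA for plain vectors).
#' @export
heritability <- function(fit) {
  if (inherits(fit, "varfit")) return(fit$ratios)
  v <- unlist(fit)
  tot <- sum(v)
  if (tot <= 0) stop("heritability(): total variance is zero")
  data.frame(term = names(v), ratio = as.numeric(v) / tot, se = NA_real_,
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested REML fits
#'
#' Twice the difference in restricted log-likelihoods, referred to a
#' chi-square with \code{df} degrees of freedom (default 1, the convention
#' for testing one variance component; conservative at the boundary).
#'
#' @param fit_full,fit_reduced \code{varfit}s (or anything with a
#'   \code{loglik} element) fitted to the same records and fixed effects.
#' @param df degrees of freedom.
#' @return list \code{chi2, df, p}.
#' @export
lrt <- function(fit_full, fit_reduced, df = 1L) {
  d <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (d < -1e-6) {
    warning("full model log-likelihood below reduced model's; optimizer failure?")
  }
  chi2 <- max(0, d)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Wald test of fixed effects
#'
#' Joint chi-square test that the named fixed-effect columns are zero; a
#' single column also reports \eqn{Z = \hat\beta/SE}.
#'
#' @param fit a \code{varfit}.
#' @param term regular expression or exact names selecting columns of the
#'   design.
#' @return list \code{statistic, df, p, z} (\code{z} is NA for joint tests).
#' @export
wald_fixed <- function(fit, term) {
  nm <- fit$beta$term
  idx <- which(nm %in% term)
  if (!length(idx)) idx <- grep(term[1], nm)
  if (!length(idx)) stop("no fixed-effect column matches '", term, "'")
  b <- fit$beta$estimate[idx]
  Vb <- fit$C_beta[idx, idx, drop = FALSE]
  stat <- drop(crossprod(b, solve(Vb, b)))
  z <- if (length(idx) == 1L) b / sqrt(Vb[1, 1]) else NA_real_
  list(statistic = stat, df = length(idx),
       p = stats::pchisq(stat, length(idx), lower.tail = FALSE), z = z)
}

## build the stacked cross-sex structure shared by all bivariate modes
.bivar_structure <- function(pheno, K, response, id, sex_col, fixed) {
  sex <- as.character(pheno[[sex_col]])
  stopifnot(all(sex %in% c("F", "M")))
  y <- pheno[[response]]
  ids <- as.character(pheno[[id]])
  lev <- sort(unique(ids))
  sex_of <- sex[match(lev, ids)]
  if (!is.null(K)) K <- K[lev, lev]
  sf <- as.numeric(sex_of == "F")
  sm <- 1 - sf
  Kff <- K * tcrossprod(sf)
  Kmm <- K * tcrossprod(sm)
  Kfm <- K * (tcrossprod(sf, sm) + tcrossprod(sm, sf))
  dimnames(Kff) <- dimnames(Kmm) <- dimnames(Kfm) <- list(lev, lev)
  If <- diag(sf); Im <- diag(sm)
  dimnames(If) <- dimnames(Im) <- list(lev, lev)
  # per-trait fixed effects: intercept (+ covariates) within each sex
  fixed <- fixed[fixed %in% names(pheno)]
  Xs <- lapply(c("F", "M"), function(s) {
    base <- cbind(as.numeric(sex == s))
    colnames(base) <- paste0("(Intercept).", s)
    for (f in fixed) {
      v <- cbind(as.numeric(sex == s) * as.numeric(pheno[[f]]))
      colnames(v) <- paste0(f, ".", s)
      base <- cbind(base, v)
    }
    base
  })
  X <- do.call(cbind, Xs)
  list(y = y, X = X, ids = ids, sex = sex,
       Kff = Kff, Kmm = Kmm, Kfm = Kfm, If = If, Im = Im)
}

#' Bivariate cross-sex animal model of ACC
#'
#' Treats female and male ACC as two traits measured on disjoint
#' individuals and fits the 2-trait additive covariance structure with
#' heterogeneous variances and cross-sex genetic correlation \eqn{r_A}
#' (correlation-with-heterogeneous-variances error structure), sex-specific
#' permanent-environment and residual variances, and per-trait fixed
#' effects. Modes: \code{"free"} (\eqn{r_A} unconstrained, fitted by
#' AI-REML), \code{"rA0"} and \code{"rA0.999"} (\eqn{r_A} fixed at 0 or
#' 0.999), and \code{"equal_VA"} (additive variances constrained equal,
#' correlation free). Constrained modes are compared to the free fit with
#' [lrt()].
#'
#' @param pheno data frame of gamete records with id, sex and response.
#' @param K relatedness matrix over all focal individuals.
#' @param mode constraint mode.
#' @param response,id,sex_col column names.
#' @param fixed per-trait fixed covariate columns (default genomic
#'   inbreeding if present).
#' @param max_iter,tol passed to the free-mode AI-REML.
#' @return list of class \code{bivarfit}: \code{va} (named F/M), \code{cov_a},
#'   \code{rA}, \code{pe}, \code{ve}, \code{loglik}, \code{mode},
#'   \code{converged}; free mode also carries the underlying \code{varfit}.
#' @export
reml_bivariate <- function(pheno, K, mode = c("free", "rA0", "rA0.999",
                                              "equal_VA"),
                           response = "acc", id = "fid", sex_col = "sex",
                           fixed = "fiii", max_iter = 200L, tol = 1e-8) {
  mode <- match.arg(mode)
  bs <- .bivar_structure(pheno, K, response, id, sex_col, fixed)

  # all modes go through a bounded profile optimization so that the
  # correlation constraint |rA| <= 1 (not implied by positive definiteness
  # when the GRM is near-diagonal) is honored exactly
  st <- .reml_structure(bs$y, bs$X, random = list(
    u = list(levels = bs$ids,
             K = list(aF = bs$Kff, aM = bs$Kmm, aFM = bs$Kfm,
                      peF = bs$If, peM = bs$Im),
             positive = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  ), residual_groups = bs$sex)
  vp <- stats::var(bs$y)
  r_cap <- 0.9999
  # parameter layouts: variances on the log scale, correlation via tanh
  make_theta <- switch(mode,
    free = function(par) {
      vaf <- exp(par[1]); vam <- exp(par[2])
      r <- r_cap * tanh(par[3])
      c(vaf, vam, r * sqrt(vaf * vam), exp(par[4:7]))
    },
    rA0 = function(par) {
      c(exp(par[1]), exp(par[2]), 0, exp(par[3:6]))
    },
    `rA0.999` = function(par) {
      vaf <- exp(par[1]); vam <- exp(par[2])
      c(vaf, vam, 0.999 * sqrt(vaf * vam), exp(par[3:6]))
    },
    equal_VA = function(par) {
      va <- exp(par[1])
      r <- r_cap * tanh(par[2])
      c(va, va, r * va, exp(par[3:6]))
    }
  )
  nll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 40)) return(1e10)
    ev <- .reml_eval(st, make_theta(par), derivs = FALSE)
    if (!ev$ok) return(1e10)
    -ev$loglik
  }
  lv0 <- log(0.15 * vp)
  p0 <- switch(mode,
    free = c(lv0, lv0, 0.3, rep(log(0.1 * vp), 2), rep(log(0.6 * vp), 2)),
    rA0 = c(lv0, lv0, rep(log(0.1 * vp), 2), rep(log(0.6 * vp), 2)),
    `rA0.999` = c(lv0, lv0, rep(log(0.1 * vp), 2), rep(log(0.6 * vp), 2)),
    equal_VA = c(lv0, 0.3, rep(log(0.1 * vp), 2), rep(log(0.6 * vp), 2))
  )
  opt <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  # polish with a restart (Nelder-Mead can stall on ridges)
  opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  th <- make_theta(opt$par)
  rA <- switch(mode,
    free = r_cap * tanh(opt$par[3]),
    rA0 = 0,
    `rA0.999` = 0.999,
    equal_VA = r_cap * tanh(opt$par[2])
  )
  if (mode %in% c("free", "equal_VA") && (th[1] <= 1e-8 || th[2] <= 1e-8)) {
    rA <- NA_real_ # a sex without additive variance leaves rA undefined
  }
  out <- list(va = c(F = th[1], M = th[2]), cov_a = th[3], rA = rA,
              pe = c(F = th[4], M = th[5]), ve = c(F = th[6], M = th[7]),
              loglik = -opt$value, mode = mode,
              converged = opt$convergence == 0L, fit = NULL)
  class(out) <- "bivarfit"
  out
}

#' @export
print.bivarfit <- function(x, ...) {
  cat("Bivariate cross-sex animal model (mode:", x$mode, ")\n")
  cat(sprintf("  VA(F) = %.4f  VA(M) = %.4f  cov = %.4f  rA = %.4f\n",
              x$va["F"], x$va["M"], x$cov_a, x$rA))
  cat(sprintf("  logLik = %.4f  converged: %s\n", x$loglik, x$converged))
  invisible(x)
}
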