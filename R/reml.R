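## REML engine for animal models with individual-level random effects.
##
## Every model in this package has the form
##   y = X beta + Z u + e,   u ~ N(0, G(theta)),  e ~ N(0, R(theta))
## where Z is a record -> level incidence built from one or more "blocks"
## (each block a factor mapping records to levels), G is block-diagonal with
## each block a non-negative combination of known covariance matrices
## (GRMs, pedigree A, identity) plus optional unconstrained covariance
## components (for cross-sex additive covariance), and R is diagonal with a
## variance per residual group. Because Z is an indicator matrix, all REML
## quantities reduce to q-dimensional linear algebra via the Woodbury
## identity (q = total levels), so average-information iterations cost
## O(q^3 + n) rather than O(n^3).

## --- structure -------------------------------------------------------------

.reml_structure <- function(y, X, random, residual_groups = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  # canonicalize terms; merge terms sharing a level vector into one block
  blocks <- list()
  comp_names <- character()
  comp_block <- integer()
  comp_positive <- logical()
  comp_K <- list()
  for (nm in names(random)) {
    term <- random[[nm]]
    lev_raw <- as.character(term$levels)
    stopifnot(length(lev_raw) == n)
    key <- paste(lev_raw, collapse = "\r")
    b <- match(key, vapply(blocks, `[[`, "", "key"))
    if (is.na(b)) {
      lev_names <- sort(unique(lev_raw))
      blocks[[length(blocks) + 1L]] <- list(
        key = key, lev_names = lev_names,
        lev_int = match(lev_raw, lev_names), q = length(lev_names)
      )
      b <- length(blocks)
    }
    Ks <- term$K
    if (is.null(Ks)) Ks <- list(NULL)
    if (is.matrix(Ks)) Ks <- list(Ks)
    pos <- term$positive
    if (is.null(pos)) pos <- rep(TRUE, length(Ks))
    knames <- names(Ks)
    if (is.null(knames)) knames <- rep("", length(Ks))
    for (ci in seq_along(Ks)) {
      K <- Ks[[ci]]
      lev_names <- blocks[[b]]$lev_names
      if (!is.null(K)) {
        if (is.null(rownames(K))) {
          stopifnot(nrow(K) == blocks[[b]]$q)
        } else {
          miss <- setdiff(lev_names, rownames(K))
          if (length(miss)) stop("covariance matrix for term '", nm,
                                 "' lacks levels: ", paste(utils::head(miss, 5), collapse = ", "))
          K <- K[lev_names, lev_names]
        }
        K <- unname(as.matrix(K))
      }
      comp_names <- c(comp_names,
                      if (nzchar(knames[ci])) paste0(nm, ".", knames[ci]) else nm)
      comp_block <- c(comp_block, b)
      comp_positive <- c(comp_positive, pos[ci])
      comp_K[length(comp_K) + 1L] <- list(K) # K may be NULL (identity)
    }
  }
  offs <- c(0L, cumsum(vapply(blocks, `[[`, 0L, "q")))
  qtot <- offs[length(offs)]

  if (is.null(residual_groups)) residual_groups <- rep("residual", n)
  rg <- factor(residual_groups)
  rg_names <- if (nlevels(rg) == 1L) "residual" else
    paste0("residual.", levels(rg))

  list(
    y = y, X = X, n = n, p = ncol(X),
    blocks = blocks, offs = offs, qtot = qtot,
    comp_names = comp_names, comp_block = comp_block,
    comp_positive = comp_positive, comp_K = comp_K,
    rg_int = as.integer(rg), rg_n = nlevels(rg), rg_names = rg_names,
    theta_names = c(comp_names, rg_names)
  )
}

## Z' u  (u vector or matrix over records) -> q-dim
.zt <- function(st, u) {
  u <- as.matrix(u)
  out <- matrix(0, st$qtot, ncol(u))
  for (b in seq_along(st$blocks)) {
    blk <- st$blocks[[b]]
    rs <- rowsum(u, blk$lev_int, reorder = TRUE)
    out[st$offs[b] + seq_len(blk$q), ] <- rs
  }
  out
}

## Z v (v over levels) -> n-dim
.zv <- function(st, v) {
  v <- as.matrix(v)
  out <- matrix(0, st$n, ncol(v))
  for (b in seq_along(st$blocks)) {
    blk <- st$blocks[[b]]
    out <- out + v[st$offs[b] + blk$lev_int, , drop = FALSE]
  }
  out
}

## Z' diag(w) Z  -> qtot x qtot
.ztwz <- function(st, w) {
  Tm <- matrix(0, st$qtot, st$qtot)
  nb <- length(st$blocks)
  for (a in seq_len(nb)) {
    for (b in a:nb) {
      ba <- st$blocks[[a]]; bb <- st$blocks[[b]]
      f <- (ba$lev_int - 1L) * bb$q + bb$lev_int
      s <- rowsum(w, f, reorder = TRUE)
      fv <- as.integer(rownames(s))
      ka <- (fv - 1L) %/% bb$q + 1L
      kb <- (fv - 1L) %% bb$q + 1L
      Tab <- matrix(0, ba$q, bb$q)
      Tab[cbind(ka, kb)] <- s
      ra <- st$offs[a] + seq_len(ba$q)
      rb <- st$offs[b] + seq_len(bb$q)
      Tm[ra, rb] <- Tm[ra, rb] + Tab
      if (a != b) Tm[rb, ra] <- Tm[rb, ra] + t(Tab)
    }
  }
  Tm
}

## diag(Z W Z') over records
.zwz_diag <- function(st, W) {
  out <- numeric(st$n)
  nb <- length(st$blocks)
  for (a in seq_len(nb)) {
    ia <- st$offs[a] + st$blocks[[a]]$lev_int
    for (b in seq_len(nb)) {
      ib <- st$offs[b] + st$blocks[[b]]$lev_int
      out <- out + W[cbind(ia, ib)]
    }
  }
  out
}

.assemble_G <- function(st, theta) {
  G <- matrix(0, st$qtot, st$qtot)
  nc <- length(st$comp_names)
  for (ci in seq_len(nc)) {
    b <- st$comp_block[ci]
    idx <- st$offs[b] + seq_len(st$blocks[[b]]$q)
    K <- st$comp_K[[ci]]
    if (is.null(K)) {
      G[cbind(idx, idx)] <- G[cbind(idx, idx)] + theta[ci]
    } else {
      G[idx, idx] <- G[idx, idx] + theta[ci] * K
    }
  }
  G
}

## one REML evaluation; returns loglik and (optionally) derivative pieces
.reml_eval <- function(st, theta, derivs = TRUE) {
  nc <- length(st$comp_names)
  th_r <- theta[nc + seq_len(st$rg_n)]
  if (any(th_r <= 0)) return(list(ok = FALSE))
  r_rec <- th_r[st$rg_int]
  Ri <- 1 / r_rec

  G <- .assemble_G(st, theta)
  cholG <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(cholG)) return(list(ok = FALSE))
  Ginv <- chol2inv(cholG)
  logdetG <- 2 * sum(log(diag(cholG)))

  ZtRiZ <- .ztwz(st, Ri)
  M <- Ginv + ZtRiZ
  cholM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cholM)) return(list(ok = FALSE))
  W <- chol2inv(cholM)
  logdetM <- 2 * sum(log(diag(cholM)))

  y <- st$y; X <- st$X
  XR <- X * Ri
  XtRiX <- crossprod(X, XR)
  XtRiy <- crossprod(XR, y)
  ytRiy <- sum(y * y * Ri)
  ZtRiX <- .zt(st, XR)
  ZtRiy <- .zt(st, y * Ri)

  WZRX <- W %*% ZtRiX
  WZRy <- W %*% ZtRiy
  XtViX <- XtRiX - crossprod(ZtRiX, WZRX)
  XtViy <- XtRiy - crossprod(ZtRiX, WZRy)
  cholXVX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cholXVX)) return(list(ok = FALSE))
  C <- chol2inv(cholXVX)
  beta <- drop(C %*% XtViy)
  ytViy <- ytRiy - sum(ZtRiy * WZRy)
  ytPy <- drop(ytViy - crossprod(XtViy, beta))

  logdetV <- logdetG + logdetM + sum(log(r_rec))
  loglik <- -0.5 * (logdetV + 2 * sum(log(diag(cholXVX))) + ytPy +
                      (st$n - st$p) * log(2 * pi))
  out <- list(ok = TRUE, loglik = loglik, beta = beta, C = C,
              W = W, Ri = Ri, ZtRiy = ZtRiy, WZRy = WZRy, theta = theta)
  if (!derivs) return(out)

  ZtViX <- ZtRiX - ZtRiZ %*% WZRX
  ZtViy <- ZtRiy - ZtRiZ %*% WZRy
  ZtViZ <- ZtRiZ - ZtRiZ %*% (W %*% ZtRiZ)
  ZtPy <- drop(ZtViy - ZtViX %*% beta)
  ZtPZ <- ZtViZ - ZtViX %*% tcrossprod(C, ZtViX)
  ViX <- XR - Ri * .zv(st, WZRX)
  Viy <- drop(y * Ri - Ri * .zv(st, WZRy))
  Py <- drop(Viy - ViX %*% beta)
  diagVi <- Ri - Ri^2 * .zwz_diag(st, W)
  diagP <- diagVi - rowSums((ViX %*% C) * ViX)

  nc <- length(st$comp_names)
  t_tot <- nc + st$rg_n
  grad <- numeric(t_tot)
  S <- matrix(0, st$n, t_tot)
  for (ci in seq_len(nc)) {
    b <- st$comp_block[ci]
    idx <- st$offs[b] + seq_len(st$blocks[[b]]$q)
    u <- ZtPy[idx]
    K <- st$comp_K[[ci]]
    if (is.null(K)) {
      trPdV <- sum(diag(ZtPZ)[idx])
      Ku <- u
    } else {
      trPdV <- sum(K * ZtPZ[idx, idx])
      Ku <- drop(K %*% u)
    }
    grad[ci] <- -0.5 * (trPdV - sum(u * Ku))
    vfull <- numeric(st$qtot)
    vfull[idx] <- Ku
    S[, ci] <- .zv(st, vfull)
  }
  for (g in seq_len(st$rg_n)) {
    sel <- st$rg_int == g
    grad[nc + g] <- -0.5 * (sum(diagP[sel]) - sum(Py[sel]^2))
    S[, nc + g] <- Py * sel
  }
  # average-information matrix: 0.5 * S' P S
  ViS <- S * Ri - Ri * .zv(st, W %*% .zt(st, S * Ri))
  PS <- ViS - ViX %*% (C %*% crossprod(ViX, S))
  AI <- 0.5 * crossprod(S, PS)
  AI <- (AI + t(AI)) / 2

  out$ZtPy <- ZtPy; out$ZtPZ <- ZtPZ; out$Py <- Py; out$ViX <- ViX
  out$grad <- grad; out$AI <- AI; out$diagP <- diagP
  out
}

## --- fitting ---------------------------------------------------------------

#' Fit a variance-component animal model by restricted maximum likelihood
#'
#' Average-information REML with step-halving and an EM-style fallback, on
#' models whose random effects are indexed by record-to-level factors with
#' known level covariance matrices (GRM, pedigree relationship, identity).
#' Components are constrained non-negative (pinned to a small boundary when
#' updates push them negative twice); components declared
#' \code{positive = FALSE} (covariance terms) are unconstrained. The
#' restricted log-likelihood never decreases across accepted iterations.
#'
#' @param y numeric response (one element per record).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param random named list of random terms. Each term is a list with
#'   \code{levels} (length-n vector mapping records to levels) and optional
#'   \code{K}: a covariance matrix over levels with dimnames (or a named
#'   list of such matrices, each getting its own variance component, with
#'   optional logical vector \code{positive}); \code{K = NULL} means
#'   identity (e.g. a permanent-environment effect).
#' @param residual_groups optional factor splitting records into residual
#'   variance groups (heterogeneous residuals, e.g. by sex).
#' @param start optional named start values for the components.
#' @param max_iter,tol iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param fixed_theta optional named vector of components to hold fixed.
#' @return object of class \code{varfit}: \code{components} (estimates and
#'   SEs, including residual), \code{beta} (fixed-effect solutions, SEs),
#'   \code{loglik}, \code{converged}, \code{boundary}, \code{ratios}
#'   (variance proportions with delta-method SEs), plus solver internals
#'   used by the association scans.
#' @export
reml_fit <- function(y, X = NULL, random, residual_groups = NULL,
                     start = NULL, max_iter = 200L, tol = 1e-8,
                     fixed_theta = NULL) {
  st <- .reml_structure(y, X, random, residual_groups)
  nc <- length(st$comp_names)
  t_tot <- nc + st$rg_n
  vp <- stats::var(stats::lm.fit(st$X, st$y)$residuals)
  if (!is.finite(vp) || vp <= 0) vp <- stats::var(y) + 1e-8
  lb <- 1e-10 * vp

  theta <- numeric(t_tot)
  npos <- sum(st$comp_positive) + st$rg_n
  theta[seq_len(nc)][st$comp_positive] <- 0.5 * vp / max(npos - st$rg_n, 1L)
  theta[seq_len(nc)][!st$comp_positive] <- 0
  theta[nc + seq_len(st$rg_n)] <- 0.5 * vp
  names(theta) <- st$theta_names
  if (!is.null(start)) theta[names(start)] <- start
  fixed_idx <- integer()
  if (!is.null(fixed_theta)) {
    fixed_idx <- match(names(fixed_theta), st$theta_names)
    theta[fixed_idx] <- fixed_theta
  }
  positive <- c(st$comp_positive, rep(TRUE, st$rg_n))

  ev <- .reml_eval(st, theta)
  if (!ev$ok) stop("REML: starting values give an invalid covariance")
  trace <- ev$loglik
  neg_count <- integer(t_tot)
  pinned <- rep(FALSE, t_tot)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    free <- setdiff(which(!pinned), fixed_idx)
    if (!length(free)) break
    AIf <- ev$AI[free, free, drop = FALSE]
    delta <- tryCatch(
      solve(AIf + diag(1e-8 * max(diag(AIf), 1), length(free)),
            ev$grad[free]),
      error = function(e) NULL
    )
    if (is.null(delta)) { # EM-style fallback direction
      delta <- 2 * theta[free]^2 * ev$grad[free] / st$n
    }
    step <- 1
    accepted <- FALSE
    for (h in seq_len(25L)) {
      prop <- theta
      prop[free] <- theta[free] + step * delta
      went_neg <- positive & prop < lb & !pinned
      prop[seq_len(t_tot)][went_neg] <- lb
      ev2 <- .reml_eval(st, prop)
      if (ev2$ok && ev2$loglik >= ev$loglik - 1e-10) {
        neg_count[went_neg] <- neg_count[went_neg] + 1L
        pinned[neg_count >= 2L & positive] <- TRUE
        prop[pinned] <- lb
        dll <- ev2$loglik - ev$loglik
        theta <- prop
        ev <- ev2
        trace <- c(trace, ev$loglik)
        accepted <- TRUE
        if (abs(dll) < tol) converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { # try a pure EM step before giving up
      prop <- theta
      prop[free] <- theta[free] + 2 * theta[free]^2 * ev$grad[free] / st$n
      prop[positive & prop < lb] <- lb
      ev2 <- .reml_eval(st, prop)
      if (ev2$ok && ev2$loglik >= ev$loglik - 1e-10) {
        theta <- prop; ev <- ev2; trace <- c(trace, ev$loglik)
      } else {
        converged <- TRUE # cannot improve: local optimum within tolerance
      }
    }
    if (converged) break
  }

  .varfit_finish(st, ev, theta, trace, converged, pinned, lb)
}

.varfit_finish <- function(st, ev, theta, trace, converged, pinned, lb) {
  nc <- length(st$comp_names)
  t_tot <- nc + st$rg_n
  cov_theta <- tryCatch(solve(ev$AI), error = function(e) {
    matrix(NA_real_, t_tot, t_tot)
  })
  se_theta <- sqrt(pmax(diag(cov_theta), 0))
  kappa_ai <- tryCatch(kappa(ev$AI), error = function(e) Inf)

  # variance proportions over all non-negative components + residual
  var_idx <- c(which(st$comp_positive), nc + seq_len(st$rg_n))
  tot <- sum(theta[var_idx])
  ratios <- theta[var_idx] / tot
  Jr <- matrix(0, length(var_idx), t_tot)
  for (k in seq_along(var_idx)) {
    Jr[k, var_idx] <- -theta[var_idx[k]] / tot^2
    Jr[k, var_idx[k]] <- Jr[k, var_idx[k]] + 1 / tot
  }
  ratio_se <- sqrt(pmax(diag(Jr %*% cov_theta %*% t(Jr)), 0))

  beta_se <- sqrt(diag(ev$C))
  structure(list(
    components = data.frame(
      term = st$theta_names, estimate = unname(theta), se = unname(se_theta),
      pinned = unname(pinned), stringsAsFactors = FALSE
    ),
    beta = data.frame(
      term = colnames(st$X), estimate = unname(ev$beta), se = unname(beta_se),
      z = unname(ev$beta / beta_se), stringsAsFactors = FALSE
    ),
    loglik = ev$loglik, loglik_trace = trace,
    converged = converged, boundary = any(pinned),
    ambiguous = !is.finite(kappa_ai) || kappa_ai > 1e10,
    ratios = data.frame(
      term = st$theta_names[var_idx], ratio = unname(ratios),
      se = unname(ratio_se), stringsAsFactors = FALSE
    ),
    theta = theta, cov_theta = cov_theta,
    n = st$n, p = st$p,
    C_beta = ev$C,
    internals = list(st = st, ev = ev)
  ), class = "varfit")
}

#' @export
print.varfit <- function(x, ...) {
  cat("REML animal model fit: n =", x$n, " logLik =",
      formatC(x$loglik, digits = 6, format = "f"),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("\nVariance components:\n")
  print(x$components, row.names = FALSE)
  cat("\nProportions of phenotypic variance:\n")
  print(x$ratios, row.names = FALSE)
  cat("\nFixed effects:\n")
  print(x$beta, row.names = FALSE)
  invisible(x)
}
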