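#' Build five-member sub-pedigrees for gamete phasing
#'
#' For each focal individual (FID) and offspring pair, the phaseable unit is
#' the FID, its mate (the offspring's other parent), the FID's sire and dam,
#' and the offspring. A pair is kept only when all five members are
#' genotyped.
#'
#' @param pedigree data frame with \code{id, sire, dam, sex}.
#' @param genotyped_ids character vector of genotyped individuals.
#' @return data frame \code{fid, mate, sire, dam, offspring, fid_sex},
#'   ordered by (fid, offspring); the number of pairs skipped for missing
#'   genotypes is attached as attribute \code{n_skipped}.
#' @export
build_subpedigrees <- function(pedigree, genotyped_ids) {
  gset <- unique(genotyped_ids)
  rows <- list()
  n_skipped <- 0L
  has_parents <- !is.na(pedigree$sire) & !is.na(pedigree$dam)
  for (i in which(has_parents)) {
    off <- pedigree$id[i]
    for (role in c("sire", "dam")) {
      fid <- pedigree[[role]][i]
      mate <- if (role == "sire") pedigree$dam[i] else pedigree$sire[i]
      fr <- match(fid, pedigree$id)
      if (is.na(fr)) next
      gsire <- pedigree$sire[fr]
      gdam <- pedigree$dam[fr]
      if (is.na(gsire) || is.na(gdam)) {
        n_skipped <- n_skipped + 1L
        next
      }
      members <- c(fid, mate, gsire, gdam, off)
      if (all(members %in% gset)) {
        rows[[length(rows) + 1L]] <- data.frame(
          fid = fid, mate = mate, sire = gsire, dam = gdam, offspring = off,
          fid_sex = pedigree$sex[fr], stringsAsFactors = FALSE
        )
      } else {
        n_skipped <- n_skipped + 1L
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fid = character(), mate = character(), sire = character(),
               dam = character(), offspring = character(),
               fid_sex = character(), stringsAsFactors = FALSE)
  out <- out[order(out$fid, out$offspring), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Screen a sub-pedigree for Mendelian incompatibilities
#'
#' A parent-offspring pair is incompatible at a SNP when the two genotypes
#' share no allele (opposite homozygotes under 0/1/2 dosage coding).
#' Incompatible genotypes are set to missing in both members of the pair;
#' if the mismatching fraction of compared loci exceeds \code{threshold} for
#' any parent-offspring pair, the whole sub-pedigree is discarded.
#'
#' @param geno5 5 x SNP dosage matrix with rows
#'   \code{fid, mate, sire, dam, offspring} (in that order).
#' @param threshold maximum tolerated mismatch fraction per pair
#'   (default 0.001, i.e. 0.1\%).
#' @return list with \code{geno} (cleaned matrix), \code{discard} (logical),
#'   \code{max_fraction}, \code{n_mismatch}.
#' @export
screen_mendelian <- function(geno5, threshold = 0.001) {
  stopifnot(nrow(geno5) == 5L)
  pairs <- list(c(3L, 1L), c(4L, 1L), c(1L, 5L), c(2L, 5L))
  discard <- FALSE
  max_frac <- 0
  n_mm <- 0L
  for (pr in pairs) {
    a <- geno5[pr[1L], ]
    b <- geno5[pr[2L], ]
    comp <- !is.na(a) & !is.na(b)
    mm <- comp & (abs(a - b) == 2L)
    frac <- if (any(comp)) sum(mm) / sum(comp) else 0
    max_frac <- max(max_frac, frac)
    n_mm <- n_mm + sum(mm)
    if (frac > threshold) discard <- TRUE
    if (any(mm)) {
      geno5[pr[1L], mm] <- NA_integer_
      geno5[pr[2L], mm] <- NA_integer_
    }
  }
  list(geno = geno5, discard = discard, max_fraction = max_frac, n_mismatch = n_mm)
}

#' Phase the gamete transmitted from an FID to one offspring
#'
#' At each autosomal SNP the grandparental origin of the transmitted allele
#' is called when (a) the allele the FID passed to the offspring is
#' determined (offspring homozygous, or offspring heterozygous with the mate
#' homozygous for one of its alleles), (b) the FID is heterozygous, and (c)
#' exactly one of the FID's parents can have contributed that allele. All
#' other SNPs are uncalled.
#'
#' @param geno5 cleaned 5 x SNP dosage matrix (rows fid, mate, sire, dam,
#'   offspring) from [screen_mendelian()].
#' @param map linkage map covering the genotyped SNPs, in map order.
#' @return list (one per chromosome) of integer vectors over that
#'   chromosome's SNPs: 1 = transmitted allele of sire origin, 2 = dam
#'   origin, NA = unknown.
#' @export
phase_gamete <- function(geno5, map) {
  stopifnot(ncol(geno5) == nrow(map))
  fid <- geno5[1L, ]; mate <- geno5[2L, ]
  sire <- geno5[3L, ]; dam <- geno5[4L, ]; off <- geno5[5L, ]

  # transmitted allele from FID (0 = A, 1 = B, NA = indeterminate)
  t_all <- rep(NA_integer_, length(fid))
  t_all[!is.na(off) & off == 0L] <- 0L
  t_all[!is.na(off) & off == 2L] <- 1L
  het <- !is.na(off) & off == 1L & !is.na(mate)
  t_all[het & mate == 0L] <- 1L # mate gave A, FID gave B
  t_all[het & mate == 2L] <- 0L

  informative <- !is.na(fid) & fid == 1L & !is.na(t_all)

  # a parent "can" have contributed the allele unless its genotype excludes it
  can_give <- function(par, t) {
    ifelse(is.na(par), TRUE, ifelse(t == 0L, par <= 1L, par >= 1L))
  }
  sire_can <- can_give(sire, t_all)
  dam_can <- can_give(dam, t_all)
  origin <- rep(NA_integer_, length(fid))
  one <- informative & sire_can & !dam_can
  two <- informative & dam_can & !sire_can
  origin[one] <- 1L
  origin[two] <- 2L
  split(origin, map$chr)
}

## run-level helpers on one chromosome's origin calls -----------------------

## returns indices (into the informative subset) belonging to length-1 runs
.singleton_idx <- function(o) {
  r <- rle(o)
  if (length(r$lengths) == 0L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$lengths == 1L]
}

#' Call crossovers from phase vectors with quality control
#'
#' The calling pipeline is: (1) a crossover is called between consecutive
#' informative SNPs with different grandparental origins; (2) gametes whose
#' raw autosomal count exceeds \code{max_acc} are discarded as pervasive
#' phasing errors; (3) phase runs consisting of a single SNP are masked and
#' crossovers re-called; (4) any internal run whose flanking informative
#' markers (the last SNP of the preceding run and the first SNP of the
#' following run) span \code{<= double_xover_cM} is masked, iterating to a
#' fixed point, and crossovers re-called; (5) per-chromosome counts and the
#' total autosomal crossover count (ACC) are computed. A run touching a
#' chromosome end is never treated as a short double crossover. Masking can
#' only lower the count.
#'
#' @param phase_vectors per-chromosome origin vectors from [phase_gamete()]
#'   (or [true_phase_vectors()]).
#' @param map linkage map (defines cM positions; same SNP order).
#' @param double_xover_cM span threshold for masking internal double
#'   crossovers (default 10).
#' @param max_acc raw-count discard threshold (default 60).
#' @return list with \code{counts} (per-chromosome), \code{acc},
#'   \code{raw_acc}, \code{high_count_discard}, \code{n_singletons_masked},
#'   \code{n_short_doubles_masked}, and \code{intervals} (data frame of
#'   flanking-SNP crossover intervals).
#' @export
call_crossovers <- function(phase_vectors, map, double_xover_cM = 10,
                            max_acc = 60) {
  chrs <- sort(unique(map$chr))
  stopifnot(length(phase_vectors) == length(chrs))
  pos_by_chr <- split(map$cM, map$chr)
  snp_by_chr <- split(map$snp, map$chr)

  per_chr <- vector("list", length(chrs))
  raw_counts <- integer(length(chrs))
  for (ci in seq_along(chrs)) {
    o_full <- phase_vectors[[ci]]
    keep <- !is.na(o_full)
    per_chr[[ci]] <- list(
      o = o_full[keep],
      pos = pos_by_chr[[ci]][keep],
      snp = snp_by_chr[[ci]][keep]
    )
    r <- rle(per_chr[[ci]]$o)
    raw_counts[ci] <- max(length(r$lengths) - 1L, 0L)
  }
  raw_acc <- sum(raw_counts)

  out <- list(
    raw_acc = raw_acc, raw_counts = raw_counts,
    high_count_discard = raw_acc > max_acc,
    n_singletons_masked = 0L, n_short_doubles_masked = 0L
  )
  if (out$high_count_discard) {
    out$counts <- rep(NA_integer_, length(chrs))
    out$acc <- NA_integer_
    out$intervals <- NULL
    return(out)
  }

  n_singl <- 0L
  n_dbl <- 0L
  for (ci in seq_along(chrs)) {
    v <- per_chr[[ci]]
    # (3) mask single-SNP runs, one pass
    sidx <- .singleton_idx(v$o)
    if (length(sidx)) {
      n_singl <- n_singl + length(sidx)
      v$o <- v$o[-sidx]; v$pos <- v$pos[-sidx]; v$snp <- v$snp[-sidx]
    }
    # (4) mask short internal double-crossover runs until stable
    repeat {
      r <- rle(v$o)
      k <- length(r$lengths)
      if (k < 3L) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      bad <- integer()
      for (j in 2L:(k - 1L)) {
        span <- v$pos[starts[j + 1L]] - v$pos[ends[j - 1L]]
        if (span <= double_xover_cM) bad <- c(bad, j)
      }
      if (!length(bad)) break
      drop <- unlist(lapply(bad, function(j) starts[j]:ends[j]))
      n_dbl <- n_dbl + length(bad)
      v$o <- v$o[-drop]; v$pos <- v$pos[-drop]; v$snp <- v$snp[-drop]
    }
    per_chr[[ci]] <- v
  }

  counts <- integer(length(chrs))
  ivals <- list()
  for (ci in seq_along(chrs)) {
    v <- per_chr[[ci]]
    r <- rle(v$o)
    counts[ci] <- max(length(r$lengths) - 1L, 0L)
    if (counts[ci] > 0L) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_len(length(r$lengths) - 1L)) {
        ivals[[length(ivals) + 1L]] <- data.frame(
          chromosome = chrs[ci],
          left_snp = v$snp[ends[j]], right_snp = v$snp[starts[j + 1L]],
          span_cM = v$pos[starts[j + 1L]] - v$pos[ends[j]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out$counts <- counts
  out$acc <- sum(counts)
  out$n_singletons_masked <- n_singl
  out$n_short_doubles_masked <- n_dbl
  out$intervals <- if (length(ivals)) do.call(rbind, ivals) else NULL
  out
}

#' Run the full crossover-calling pipeline over a genotyped pedigree
#'
#' Convenience wrapper: builds sub-pedigrees, applies the Mendelian screen,
#' phases each transmitted gamete and calls crossovers with QC.
#'
#' @param genotypes id x SNP dosage matrix.
#' @param pedigree data frame with \code{id, sire, dam, sex}.
#' @param map linkage map.
#' @param mendel_threshold,double_xover_cM,max_acc QC parameters.
#' @return list of class \code{acc_callset}: \code{records} (one row per
#'   gamete: fid, offspring, sex, acc, raw_acc, QC flags, pass),
#'   \code{counts} (pass-records x chromosomes matrix), \code{intervals}
#'   (crossover intervals of passing records), \code{subpedigrees}.
#' @export
call_acc <- function(genotypes, pedigree, map, mendel_threshold = 0.001,
                     double_xover_cM = 10, max_acc = 60) {
  subs <- build_subpedigrees(pedigree, rownames(genotypes))
  chrs <- sort(unique(map$chr))
  recs <- vector("list", nrow(subs))
  cnts <- vector("list", nrow(subs))
  ivals <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    s <- subs[i, ]
    g5 <- genotypes[c(s$fid, s$mate, s$sire, s$dam, s$offspring), ,
                    drop = FALSE]
    scr <- screen_mendelian(g5, mendel_threshold)
    if (scr$discard) {
      recs[[i]] <- data.frame(
        fid = s$fid, offspring = s$offspring, sex = s$fid_sex,
        acc = NA_integer_, raw_acc = NA_integer_, mendel_discard = TRUE,
        high_count_discard = FALSE, n_singletons_masked = 0L,
        n_short_doubles_masked = 0L, pass = FALSE, stringsAsFactors = FALSE
      )
      next
    }
    pv <- phase_gamete(scr$geno, map)
    cc <- call_crossovers(pv, map, double_xover_cM, max_acc)
    recs[[i]] <- data.frame(
      fid = s$fid, offspring = s$offspring, sex = s$fid_sex,
      acc = cc$acc, raw_acc = cc$raw_acc, mendel_discard = FALSE,
      high_count_discard = cc$high_count_discard,
      n_singletons_masked = cc$n_singletons_masked,
      n_short_doubles_masked = cc$n_short_doubles_masked,
      pass = !cc$high_count_discard, stringsAsFactors = FALSE
    )
    if (!cc$high_count_discard) {
      cnts[[i]] <- cc$counts
      if (!is.null(cc$intervals)) {
        ivals[[i]] <- cbind(fid = s$fid, offspring = s$offspring,
                            cc$intervals, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  pass <- which(records$pass)
  counts <- do.call(rbind, cnts[!vapply(cnts, is.null, TRUE)])
  if (!is.null(counts)) {
    colnames(counts) <- as.character(chrs)
    rownames(counts) <- paste(records$fid[pass], records$offspring[pass],
                              sep = "->")
  }
  intervals <- ivals[!vapply(ivals, is.null, TRUE)]
  intervals <- if (length(intervals)) do.call(rbind, intervals) else NULL
  structure(list(records = records, counts = counts, intervals = intervals,
                 subpedigrees = subs),
            class = "acc_callset")
}

#' Summarize called crossovers into the ACC phenotype table
#'
#' @param callset an \code{acc_callset} from [call_acc()].
#' @return list with \code{pheno} (one row per passing gamete: fid,
#'   offspring, sex, acc, plus per-chromosome counts as attribute
#'   \code{counts}) and \code{summary} (per sex and overall: NOBS, NFID,
#'   mean, SD, total crossovers).
#' @export
summarize_acc <- function(callset) {
  rec <- callset$records
  ph <- rec[rec$pass, c("fid", "offspring", "sex", "acc")]
  rownames(ph) <- NULL
  attr(ph, "counts") <- callset$counts
  blocks <- c(list(Both = ph), split(ph, ph$sex))
  summ <- do.call(rbind, lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    data.frame(
      group = nm, NOBS = nrow(b), NFID = length(unique(b$fid)),
      mean_acc = mean(b$acc), sd_acc = stats::sd(b$acc),
      n_xovers = sum(b$acc), stringsAsFactors = FALSE
    )
  }))
  list(pheno = ph, summary = summ)
}

#' trans-ACC response for a focal chromosome
#'
#' ACC minus the crossovers on the focal chromosome, so that association at
#' a SNP on that chromosome reflects genome-wide (trans) effects only.
#'
#' @param pheno phenotype table from [summarize_acc()] (needs its
#'   \code{counts} attribute) or an \code{acc_callset}.
#' @param chromosome focal chromosome id.
#' @return numeric vector aligned with the phenotype rows.
#' @export
trans_acc <- function(pheno, chromosome) {
  counts <- if (inherits(pheno, "acc_callset")) pheno$counts else
    attr(pheno, "counts")
  if (is.null(counts)) stop("per-chromosome counts unavailable")
  acc <- if (inherits(pheno, "acc_callset"))
    pheno$records$acc[pheno$records$pass] else pheno$acc
  cc <- counts[, as.character(chromosome)]
  acc - cc
}
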