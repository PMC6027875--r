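#' Simulation configuration for a pedigree meiosis dataset
#'
#' Builds the configuration object consumed by [simulate_map()],
#' [simulate_pedigree()] and [simulate_genomes()]. The defaults emulate a
#' multi-generation wild-pedigree SNP study scaled down to desk size: ~30
#' acrocentric autosomes with a known linkage map, sex-dimorphic mean
#' autosomal crossover counts (ACC), and an additive architecture of
#' crossover propensity made of one major-effect locus, a polygenic
#' background and a large per-gamete residual.
#'
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome SNPs simulated per autosome.
#' @param chr_length_cM linkage-map length of each autosome, centiMorgans.
#' @param founder_maf_range interval in (0, 0.5] from which per-SNP founder
#'   allele frequencies are drawn.
#' @param n_founder_pairs number of unrelated founder couples.
#' @param n_offspring_per_mating offspring produced by each mating.
#' @param n_generations total generations including founders (>= 3 for any
#'   focal individual to have genotyped parents and offspring).
#' @param sex_mean_acc named vector \code{c(F = ..., M = ...)} of expected
#'   ACC per meiosis for each sex.
#' @param v_qtl additive variance in ACC contributed by the planted
#'   major-effect locus.
#' @param v_poly polygenic additive variance in ACC.
#' @param v_resid per-gamete residual variance entering the Poisson mean.
#' @param qtl_chromosome,qtl_position_cM placement of the causal locus (the
#'   genotyped SNP nearest \code{qtl_position_cM} on that chromosome).
#' @param genotyping_error_rate per-genotype probability of a single-allele
#'   flip.
#' @param missing_rate per-genotype probability of a missing call.
#' @param spacing \code{"uniform"} draws SNP positions uniformly on the map;
#'   \code{"even"} spaces them evenly from 0 to \code{chr_length_cM}.
#' @param obligate_crossover if \code{TRUE}, every meiosis places at least
#'   one crossover per chromosome (off by default; no interference either
#'   way).
#' @param seed integer seed; required, there is no default.
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(n_chromosomes = 33,
                       snps_per_chromosome = 60,
                       chr_length_cM = 76,
                       founder_maf_range = c(0.05, 0.5),
                       n_founder_pairs = 30,
                       n_offspring_per_mating = 4,
                       n_generations = 4,
                       sex_mean_acc = c(F = 26.6, M = 22.2),
                       v_qtl = 3.0,
                       v_poly = 0.5,
                       v_resid = 2.0,
                       qtl_chromosome = NULL,
                       qtl_position_cM = NULL,
                       genotyping_error_rate = 0.001,
                       missing_rate = 0.005,
                       spacing = c("uniform", "even"),
                       obligate_crossover = FALSE,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("sim_config(): an explicit integer 'seed' is required")
  }
  spacing <- match.arg(spacing)
  # causal locus defaults to the middle of a mid-genome chromosome
  if (is.null(qtl_chromosome)) qtl_chromosome <- ceiling(n_chromosomes / 2)
  if (is.null(qtl_position_cM)) qtl_position_cM <- chr_length_cM / 2
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chr_length_cM = as.numeric(chr_length_cM),
    founder_maf_range = as.numeric(founder_maf_range),
    n_founder_pairs = as.integer(n_founder_pairs),
    n_offspring_per_mating = as.integer(n_offspring_per_mating),
    n_generations = as.integer(n_generations),
    sex_mean_acc = sex_mean_acc,
    v_qtl = as.numeric(v_qtl),
    v_poly = as.numeric(v_poly),
    v_resid = as.numeric(v_resid),
    qtl_chromosome = as.integer(qtl_chromosome),
    qtl_position_cM = as.numeric(qtl_position_cM),
    genotyping_error_rate = as.numeric(genotyping_error_rate),
    missing_rate = as.numeric(missing_rate),
    spacing = spacing,
    obligate_crossover = isTRUE(obligate_crossover),
    acc_floor = 0.1,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1L,
    cfg$snps_per_chromosome >= 1L,
    cfg$n_founder_pairs >= 1L,
    cfg$n_offspring_per_mating >= 1L,
    cfg$n_generations >= 2L
  )
  if (cfg$chr_length_cM <= 0) {
    stop("invalid config: chr_length_cM must be positive")
  }
  if (any(cfg$founder_maf_range <= 0) || any(cfg$founder_maf_range > 0.5) ||
      cfg$founder_maf_range[1] > cfg$founder_maf_range[2]) {
    stop("invalid config: founder_maf_range must be an interval in (0, 0.5]")
  }
  if (any(c(cfg$v_qtl, cfg$v_poly, cfg$v_resid) < 0)) {
    stop("invalid config: variances must be >= 0")
  }
  if (any(cfg$sex_mean_acc <= 0)) stop("invalid config: sex_mean_acc must be > 0")
  if (!all(c("F", "M") %in% names(cfg$sex_mean_acc))) {
    stop("invalid config: sex_mean_acc needs names 'F' and 'M'")
  }
  if (cfg$v_qtl + cfg$v_poly + cfg$v_resid + sum(cfg$sex_mean_acc) <= 0) {
    stop("invalid config: no variance anywhere")
  }
  if (cfg$qtl_chromosome > cfg$n_chromosomes) {
    stop("invalid config: qtl_chromosome exceeds n_chromosomes")
  }
  if (cfg$genotyping_error_rate < 0 || cfg$genotyping_error_rate > 1 ||
      cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    stop("invalid config: rates must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Simulate a linkage map
#'
#' SNPs are placed on each chromosome at strictly increasing cM positions in
#' \code{[0, chr_length_cM]}; base-pair positions follow the cM axis at a
#' constant 1 cM/Mb. With \code{spacing = "even"} the first and last SNP sit
#' at 0 and \code{chr_length_cM} exactly.
#'
#' @param config a [sim_config()] object.
#' @return a \code{linkage_map} data frame with columns
#'   \code{chr, snp, cM, bp} and reference/alternate allele letters.
#' @export
simulate_map <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  L <- config$chr_length_cM
  m <- config$snps_per_chromosome
  maps <- lapply(seq_len(config$n_chromosomes), function(chr) {
    if (config$spacing == "even") {
      pos <- if (m == 1L) L / 2 else seq(0, L, length.out = m)
    } else {
      pos <- sort(stats::runif(m, 0, L))
      # enforce strict increase in the (rare) event of ties
      while (anyDuplicated(pos)) pos <- sort(stats::runif(m, 0, L))
    }
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, m, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(
      chr = chr,
      snp = sprintf("snp_%d_%d", chr, seq_len(m)),
      cM = pos,
      bp = round(pos * 1e6) + 1L,
      allele_A = a1,
      allele_B = a2,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' Simulate a multi-generation pedigree
#'
#' Founder couples mate within pairs; each later generation is formed by
#' randomly pairing that generation's males and females. Sexes are assigned
#' alternately within each mating so both sexes are always represented among
#' potential focal individuals. Every non-founder has a sire and a dam of
#' opposite sex present in the pedigree.
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns \code{id, sire, dam, sex, generation};
#'   unknown parents are \code{NA}.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  rows <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("ID%05d", counter)
  }
  founders <- lapply(seq_len(config$n_founder_pairs), function(i) {
    data.frame(
      id = c(new_id(), new_id()), sire = NA_character_, dam = NA_character_,
      sex = c("M", "F"), generation = 0L, stringsAsFactors = FALSE
    )
  })
  ped <- do.call(rbind, founders)
  prev <- ped
  # founder matings are within the created pairs
  matings <- data.frame(
    sire = ped$id[ped$sex == "M"], dam = ped$id[ped$sex == "F"],
    stringsAsFactors = FALSE
  )
  for (g in seq_len(config$n_generations - 1L)) {
    kids <- lapply(seq_len(nrow(matings)), function(k) {
      n <- config$n_offspring_per_mating
      data.frame(
        id = vapply(seq_len(n), function(i) new_id(), ""),
        sire = matings$sire[k], dam = matings$dam[k],
        sex = rep_len(c("M", "F"), n),
        generation = g, stringsAsFactors = FALSE
      )
    })
    kids <- do.call(rbind, kids)
    ped <- rbind(ped, kids)
    if (g < config$n_generations - 1L) {
      males <- sample(kids$id[kids$sex == "M"])
      females <- sample(kids$id[kids$sex == "F"])
      npairs <- min(length(males), length(females))
      if (npairs == 0L) stop("pedigree simulation produced a single-sex generation")
      matings <- data.frame(
        sire = males[seq_len(npairs)], dam = females[seq_len(npairs)],
        stringsAsFactors = FALSE
      )
    }
  }
  rownames(ped) <- NULL
  ped
}

## one meiosis: crossover positions and transmitted haplotype indicator
## (1 = parent's paternal strand, 2 = maternal strand) at each SNP of one
## chromosome, given positions in cM.
meiosis_chromosome <- function(pos_cM, L, lambda_chr, obligate = FALSE) {
  n_x <- stats::rpois(1L, lambda_chr)
  if (obligate && n_x == 0L) n_x <- 1L
  xpos <- sort(stats::runif(n_x, 0, L))
  start <- sample(1:2, 1L)
  # strand at each SNP flips at every crossover position
  k <- findInterval(pos_cM, xpos)
  strand <- ifelse(k %% 2L == 0L, start, 3L - start)
  list(xpos = xpos, strand = as.integer(strand))
}

#' Simulate genotypes, true meioses and crossover propensities on a pedigree
#'
#' Founder haplotypes are drawn from per-SNP allele frequencies; each
#' meiosis draws per-chromosome crossover counts from a Poisson law whose
#' summed mean equals the parent's expected ACC (sex mean + additive
#' deviation + per-gamete residual, floored at a small positive value), with
#' crossover positions uniform on the cM axis and no interference. The
#' additive deviation is the sum of a major-locus term (the planted QTL SNP
#' dosage, scaled to contribute \code{v_qtl}) and a polygenic term
#' transmitted as mid-parent plus Mendelian-sampling noise of half
#' \code{v_poly}. Genotyping errors flip a single allele; missing calls are
#' masked. Everything is reproducible from \code{config$seed}.
#'
#' @param pedigree from [simulate_pedigree()].
#' @param map from [simulate_map()].
#' @param config a [sim_config()] object.
#' @return a \code{sim_dataset} list with elements \code{genotypes} (id x
#'   SNP dosage matrix of the B allele, NA = missing), \code{pedigree},
#'   \code{map}, \code{config} and \code{truth} (error-free haplotypes,
#'   per-meiosis crossover truth table with positions, transmitted-strand
#'   origins, and the per-individual propensity table).
#' @export
simulate_genomes <- function(pedigree, map, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  m <- nrow(map)
  ids <- pedigree$id
  n <- length(ids)
  L <- config$chr_length_cM
  chrs <- sort(unique(map$chr))
  chr_idx <- split(seq_len(m), map$chr)
  total_morgans <- config$n_chromosomes * L / 100

  p <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  # allele B is the minor-ish allele by construction; frequency p

  H1 <- matrix(0L, n, m, dimnames = list(ids, map$snp)) # from sire
  H2 <- matrix(0L, n, m, dimnames = list(ids, map$snp)) # from dam
  poly <- stats::setNames(numeric(n), ids)

  # planted QTL: genotyped SNP nearest the requested position
  qtl_rows <- chr_idx[[as.character(config$qtl_chromosome)]]
  qtl_col <- qtl_rows[which.min(abs(map$cM[qtl_rows] - config$qtl_position_cM))]
  p_q <- p[qtl_col]
  qtl_a <- if (config$v_qtl > 0) sqrt(config$v_qtl / (2 * p_q * (1 - p_q))) else 0

  ord <- order(pedigree$generation)
  row_of <- stats::setNames(seq_len(n), ids)

  meios <- list()          # truth table rows
  origin_list <- list()    # per gamete: strand origins at every SNP
  n_floored <- 0L
  n_gametes <- 0L

  expected_acc <- function(id) {
    bv <- qtl_a * (H1[id, qtl_col] + H2[id, qtl_col] - 2 * p_q) + poly[id]
    sex <- pedigree$sex[row_of[id]]
    max(config$sex_mean_acc[[sex]] + bv, config$acc_floor)
  }

  draw_gamete <- function(parent_id) {
    mu <- expected_acc(parent_id) + stats::rnorm(1L, 0, sqrt(config$v_resid))
    if (mu < config$acc_floor) {
      mu <- config$acc_floor
      n_floored <<- n_floored + 1L
    }
    n_gametes <<- n_gametes + 1L
    gam <- integer(m)
    strand <- integer(m)
    xovers <- vector("list", length(chrs))
    for (ci in seq_along(chrs)) {
      idx <- chr_idx[[ci]]
      lam <- mu * (L / 100) / total_morgans
      mz <- meiosis_chromosome(map$cM[idx], L, lam, config$obligate_crossover)
      s <- mz$strand
      gam[idx] <- ifelse(s == 1L, H1[parent_id, idx], H2[parent_id, idx])
      strand[idx] <- s
      xovers[[ci]] <- mz$xpos
    }
    list(alleles = gam, strand = strand, xovers = xovers)
  }

  for (i in ord) {
    id <- ids[i]
    if (is.na(pedigree$sire[i])) {
      H1[id, ] <- as.integer(stats::runif(m) < p)
      H2[id, ] <- as.integer(stats::runif(m) < p)
      poly[id] <- stats::rnorm(1L, 0, sqrt(config$v_poly))
    } else {
      sire <- pedigree$sire[i]
      dam <- pedigree$dam[i]
      gs <- draw_gamete(sire)
      gd <- draw_gamete(dam)
      H1[id, ] <- gs$alleles
      H2[id, ] <- gd$alleles
      poly[id] <- (poly[sire] + poly[dam]) / 2 +
        stats::rnorm(1L, 0, sqrt(config$v_poly / 2))
      for (g in list(list(par = sire, mz = gs), list(par = dam, mz = gd))) {
        key <- length(meios) + 1L
        meios[[key]] <- data.frame(
          parent = g$par, offspring = id, chromosome = chrs,
          n_xovers = vapply(g$mz$xovers, length, 1L),
          positions = I(g$mz$xovers), stringsAsFactors = FALSE
        )
        origin_list[[paste(g$par, id, sep = "->")]] <- g$mz$strand
      }
    }
  }

  if (n_gametes > 0 && n_floored / n_gametes > 0.01) {
    warning(sprintf(
      "crossover-propensity floor reached in %.1f%% of gametes; architecture may be too variable",
      100 * n_floored / n_gametes
    ))
  }

  dosage_true <- H1 + H2
  dosage <- dosage_true
  if (config$genotyping_error_rate > 0) {
    err <- matrix(stats::runif(n * m) < config$genotyping_error_rate, n, m)
    if (any(err)) {
      w <- which(err)
      cur <- dosage[w]
      flip_up <- stats::runif(length(w)) < 0.5
      newv <- ifelse(cur == 0L, 1L, ifelse(cur == 2L, 1L, ifelse(flip_up, 2L, 0L)))
      dosage[w] <- newv
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dosage[miss] <- NA_integer_
  }

  bv <- qtl_a * (dosage_true[, qtl_col] - 2 * p_q) + poly
  propensity <- data.frame(
    id = ids, sex = pedigree$sex,
    breeding_value = as.numeric(bv[ids]),
    expected_acc = pmax(config$sex_mean_acc[pedigree$sex] + bv[ids], config$acc_floor),
    stringsAsFactors = FALSE
  )

  truth <- list(
    haplo_pat = H1, haplo_mat = H2, dosage = dosage_true,
    meioses = do.call(rbind, meios),
    origins = origin_list,
    propensity = propensity,
    allele_freq = p,
    qtl_snp = map$snp[qtl_col],
    qtl_col = qtl_col,
    qtl_effect = qtl_a
  )
  structure(
    list(genotypes = dosage, pedigree = pedigree, map = map,
         truth = truth, config = config),
    class = "sim_dataset"
  )
}

#' Simulate a complete dataset (map + pedigree + genomes)
#'
#' @param config a [sim_config()] object.
#' @return a \code{sim_dataset}; see [simulate_genomes()].
#' @export
simulate_dataset <- function(config) {
  map <- simulate_map(config)
  ped <- simulate_pedigree(config)
  simulate_genomes(ped, map, config)
}

#' True autosomal crossover counts per transmitted gamete
#'
#' Aggregates the simulator truth table into one row per parent-offspring
#' transmission, the unit on which the ACC phenotype is defined.
#'
#' @param sim a \code{sim_dataset}.
#' @return data frame \code{fid, offspring, sex, acc_true} plus a
#'   \code{counts} attribute (gametes x chromosomes matrix).
#' @export
true_acc_table <- function(sim) {
  tm <- sim$truth$meioses
  key <- paste(tm$parent, tm$offspring, sep = "->")
  counts <- do.call(rbind, lapply(split(tm$n_xovers, factor(key, unique(key))),
                                  function(v) v))
  colnames(counts) <- as.character(sort(unique(tm$chromosome)))
  # split() keeps chromosome order within gamete because rows are ordered
  pk <- unique(key)
  parts <- do.call(rbind, strsplit(pk, "->", fixed = TRUE))
  sex <- sim$pedigree$sex[match(parts[, 1], sim$pedigree$id)]
  out <- data.frame(
    fid = parts[, 1], offspring = parts[, 2], sex = sex,
    acc_true = rowSums(counts[pk, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- counts[pk, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' True grandparental phase of a transmitted gamete
#'
#' Returns, for one simulated parent-to-offspring transmission, the strand of
#' origin (1 = the parent's paternally inherited strand, 2 = maternal) at
#' every SNP, split by chromosome. This is the truth standard for the
#' crossover caller.
#'
#' @param sim a \code{sim_dataset}.
#' @param parent,offspring ids of one recorded transmission.
#' @return list (one element per chromosome) of integer origin vectors.
#' @export
true_phase_vectors <- function(sim, parent, offspring) {
  key <- paste(parent, offspring, sep = "->")
  strand <- sim$truth$origins[[key]]
  if (is.null(strand)) stop("no simulated transmission ", key)
  split(strand, sim$map$chr)
}

#' Write a simulated dataset to PLINK PED/MAP and companion tables
#'
#' Writes \code{data.ped}/\code{data.map} (whitespace PLINK dialect, alleles
#' as letters, 0 = missing), \code{pedigree.csv} (id,sire,dam,sex with 0 for
#' unknown), \code{map.tsv} (chr,snp,cM,bp) and truth tables
#' (\code{truth_acc.tsv}, \code{truth_propensity.tsv}).
#'
#' @param sim a \code{sim_dataset}.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, out_dir) {
  if (is.null(sim$genotypes) || nrow(sim$genotypes) == 0L) {
    stop("write_dataset(): empty genotype table")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ped = file.path(out_dir, "data.ped"),
    map = file.path(out_dir, "data.map"),
    pedigree = file.path(out_dir, "pedigree.csv"),
    maptsv = file.path(out_dir, "map.tsv"),
    acc = file.path(out_dir, "truth_acc.tsv"),
    prop = file.path(out_dir, "truth_propensity.tsv")
  )
  write_ped_map(sim$genotypes, sim$map, sim$pedigree, paths["ped"], paths["map"])
  pedcsv <- sim$pedigree[, c("id", "sire", "dam", "sex")]
  pedcsv$sire[is.na(pedcsv$sire)] <- "0"
  pedcsv$dam[is.na(pedcsv$dam)] <- "0"
  utils::write.csv(pedcsv, paths["pedigree"], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$map[, c("chr", "snp", "cM", "bp")], paths["maptsv"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  acc <- true_acc_table(sim)
  utils::write.table(acc, paths["acc"], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$propensity, paths["prop"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write genotypes to PLINK PED/MAP text files
#'
#' @param dosage id x SNP dosage matrix (0/1/2 of the B allele, NA missing).
#' @param map linkage map with \code{chr, snp, cM, bp, allele_A, allele_B}.
#' @param pedigree data frame with id, sire, dam, sex.
#' @param ped_file,map_file output paths.
#' @export
write_ped_map <- function(dosage, map, pedigree, ped_file, map_file) {
  stopifnot(ncol(dosage) == nrow(map))
  n <- nrow(dosage)
  m <- nrow(map)
  a1 <- matrix(rep(map$allele_A, each = n), n, m)
  a2 <- a1
  a1[dosage >= 1L & !is.na(dosage)] <-
    matrix(rep(map$allele_B, each = n), n, m)[dosage >= 1L & !is.na(dosage)]
  a2[dosage == 2L & !is.na(dosage)] <-
    matrix(rep(map$allele_B, each = n), n, m)[dosage == 2L & !is.na(dosage)]
  a1[is.na(dosage)] <- "0"
  a2[is.na(dosage)] <- "0"
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, by = 2L)] <- a1
  inter[, seq(2L, 2L * m, by = 2L)] <- a2
  ids <- rownames(dosage)
  pr <- match(ids, pedigree$id)
  lead <- cbind(
    "1", ids,
    ifelse(is.na(pedigree$sire[pr]), "0", pedigree$sire[pr]),
    ifelse(is.na(pedigree$dam[pr]), "0", pedigree$dam[pr]),
    ifelse(pedigree$sex[pr] == "M", "1", "2"),
    "-9"
  )
  utils::write.table(cbind(lead, inter), ped_file, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(map$chr, map$snp, format(map$cM, trim = TRUE), map$bp),
    map_file, sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(NULL)
}

#' Read PLINK PED/MAP text files into a dosage matrix and map
#'
#' Allele B of each SNP is taken from the companion map when given (so that
#' write/read round-trips are lossless); otherwise the second allele
#' observed at the locus.
#'
#' @param ped_file,map_file paths.
#' @param alleles optional data frame \code{snp, allele_A, allele_B}.
#' @return list with \code{genotypes} (dosage matrix), \code{map},
#'   \code{pedigree} (as encoded in the PED columns).
#' @export
read_ped_map <- function(ped_file, map_file, alleles = NULL) {
  map <- utils::read.table(map_file, header = FALSE,
                           col.names = c("chr", "snp", "cM", "bp"),
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_file, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  stopifnot(ncol(ped) == 6L + 2L * m)
  ids <- ped[[2L]]
  g1 <- as.matrix(ped[, 6L + seq(1L, 2L * m, by = 2L), drop = FALSE])
  g2 <- as.matrix(ped[, 6L + seq(2L, 2L * m, by = 2L), drop = FALSE])
  if (is.null(alleles)) {
    allele_B <- vapply(seq_len(m), function(j) {
      obs <- setdiff(unique(c(g1[, j], g2[, j])), "0")
      if (length(obs) == 0L) return(NA_character_)
      sort(obs)[length(obs)]
    }, "")
  } else {
    allele_B <- alleles$allele_B[match(map$snp, alleles$snp)]
  }
  dosage <- matrix(NA_integer_, length(ids), m, dimnames = list(ids, map$snp))
  for (j in seq_len(m)) {
    miss <- g1[, j] == "0" | g2[, j] == "0"
    d <- (g1[, j] == allele_B[j]) + (g2[, j] == allele_B[j])
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  pedigree <- data.frame(
    id = ids,
    sire = ifelse(ped[[3L]] == "0", NA_character_, ped[[3L]]),
    dam = ifelse(ped[[4L]] == "0", NA_character_, ped[[4L]]),
    sex = ifelse(ped[[5L]] == "1", "M", ifelse(ped[[5L]] == "2", "F", NA)),
    stringsAsFactors = FALSE
  )
  list(genotypes = dosage, map = map, pedigree = pedigree)
}
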