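# Paired-call-set simulator. Truth genotypes are Hardy-Weinberg draws over a
# configurable MAF spectrum; each platform observes the same truth through
# its own 3x3 call-confusion matrix and independent missingness, optionally
# with MAF-dependent or phenotype-differential error mass. All randomness
# flows from one global seed through a fixed stream-splitting scheme
# (split_seed), so any stage can be regenerated stably.

#' Simulation configuration
#'
#' Defaults describe the dual-platform setting the package targets: 959
#' samples of which 464 are directly sequenced and 495 imputed, common SNPs
#' (MAF uniform on 0.05-0.5), sequence-platform missingness of 2.4% versus
#' 0.02% on the microarray, and called-error mass of order 0.1-0.3%
#' concentrated on adjacent genotype classes — together yielding overall
#' discordance levels comparable to what is observed when sequencing and
#' microarray calls are compared on shared samples.
#'
#' @param n_snps,n_samples Dimensions of the simulated call sets.
#' @param maf MAF specification: a single value (all SNPs), a length-2
#'   vector (uniform range), or a length-`n_snps` vector (per-SNP).
#' @param error_matrix_seq,error_matrix_micro 3x3 row-stochastic confusion
#'   matrices over true x observed called genotypes (AA, AB, BB), one per
#'   platform.
#' @param missing_rate_seq,missing_rate_micro Per-cell missingness
#'   probabilities, applied independently of call errors.
#' @param maf_dependence Optional function(maf) returning a multiplier
#'   applied to the off-diagonal error mass of both platforms' confusion
#'   matrices, SNP by SNP (e.g. larger errors at low MAF).
#' @param differential Optional list of two 3x3 confusion matrices named
#'   `yes` and `no`, replacing `error_matrix_seq` per sample according to
#'   the hypertension label (phenotype-differential sequence errors).
#' @param phenotype_prevalence Hypertension prevalence in (0, 1).
#' @param smoking_prevalence Ever-smoking prevalence in (0, 1).
#' @param ngs_fraction Fraction of samples whose sequence source is direct
#'   NGS (the rest imputed).
#' @param seed Integer master seed; all generators derive their streams
#'   from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 1000, n_samples = 959,
                       maf = c(0.05, 0.5),
                       error_matrix_seq = default_error_matrix("sequence"),
                       error_matrix_micro = default_error_matrix("microarray"),
                       missing_rate_seq = 0.024,
                       missing_rate_micro = 2e-4,
                       maf_dependence = NULL,
                       differential = NULL,
                       phenotype_prevalence = 0.35,
                       smoking_prevalence = 0.25,
                       ngs_fraction = 464 / 959,
                       seed = 1L) {
  stopifnot(n_snps >= 1, n_samples >= 1)
  if (!length(maf) %in% c(1, 2, n_snps)) {
    abort("`maf` must have length 1 (fixed), 2 (range) or n_snps (per-SNP)")
  }
  if (any(maf < 0 | maf > 0.5)) abort("MAF values must lie in [0, 0.5]")
  check_error_matrix(error_matrix_seq)
  check_error_matrix(error_matrix_micro)
  if (!is.null(differential)) {
    if (!is.list(differential) || !all(c("yes", "no") %in% names(differential))) {
      abort("`differential` must be a list of matrices named `yes` and `no`")
    }
    lapply(differential, check_error_matrix)
  }
  if (!is.null(maf_dependence) && !is.function(maf_dependence)) {
    abort("`maf_dependence` must be a function of MAF")
  }
  if (phenotype_prevalence <= 0 || phenotype_prevalence >= 1) {
    abort("`phenotype_prevalence` must lie strictly inside (0, 1)")
  }
  if (smoking_prevalence <= 0 || smoking_prevalence >= 1) {
    abort("`smoking_prevalence` must lie strictly inside (0, 1)")
  }
  stopifnot(missing_rate_seq >= 0, missing_rate_seq <= 1,
            missing_rate_micro >= 0, missing_rate_micro <= 1,
            ngs_fraction >= 0, ngs_fraction <= 1)
  structure(list(
    n_snps = as.integer(n_snps), n_samples = as.integer(n_samples), maf = maf,
    error_matrix_seq = error_matrix_seq, error_matrix_micro = error_matrix_micro,
    missing_rate_seq = missing_rate_seq, missing_rate_micro = missing_rate_micro,
    maf_dependence = maf_dependence, differential = differential,
    phenotype_prevalence = phenotype_prevalence,
    smoking_prevalence = smoking_prevalence,
    ngs_fraction = ngs_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default platform confusion matrices
#'
#' Row-stochastic 3x3 matrices over (AA, AB, BB): the sequence-based
#' platform mostly confuses adjacent classes (heterozygote vs minor
#' homozygote above all), the microarray is close to error-free.
#'
#' @param platform `"sequence"` or `"microarray"`.
#' @return 3x3 numeric matrix, rows = true class, columns = called class.
#' @export
default_error_matrix <- function(platform = c("sequence", "microarray")) {
  platform <- match.arg(platform)
  m <- if (platform == "sequence") {
    matrix(c(
      0.99848, 1.5e-3, 2e-5,
      1.0e-3, 0.99700, 2.0e-3,
      1.0e-4, 3.0e-3, 0.99690
    ), 3, 3, byrow = TRUE)
  } else {
    matrix(c(
      0.99948, 5e-4, 2e-5,
      5e-4, 0.99900, 5e-4,
      2e-5, 5e-4, 0.99948
    ), 3, 3, byrow = TRUE)
  }
  dimnames(m) <- list(true = gt_levels[1:3], called = gt_levels[1:3])
  m
}

check_error_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || any(m < 0)) {
    abort("error matrix must be a non-negative 3x3 matrix")
  }
  if (any(abs(rowSums(m) - 1) > 1e-12)) {
    abort("error matrix rows must each sum to 1 (tolerance 1e-12)")
  }
  invisible(m)
}

#' Derive independent sub-seeds from one master seed
#'
#' The documented stream-splitting scheme: sub-seed k is the k-th draw of
#' `sample.int` under the master seed, so each module regenerates its stream
#' without disturbing the others.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate truth genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, draws a MAF q from the configured spectrum and then genotypes
#' i.i.d. with probabilities (1-q)^2, 2q(1-q), q^2. The drawn MAFs are
#' stored in the `maf` attribute. Deterministic under the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for this stage; defaults to the first stream of the
#'   config's master seed.
#' @return A `genotype_tbl` of true calls (no missingness).
#' @export
simulate_truth <- function(cfg, seed = split_seed(cfg$seed, 4)[1]) {
  withr::with_seed(as.integer(seed), {
    q <- if (length(cfg$maf) == cfg$n_snps && cfg$n_snps != 2) cfg$maf
      else if (length(cfg$maf) == 1) rep(cfg$maf, cfg$n_snps)
      else if (length(cfg$maf) == 2) runif(cfg$n_snps, cfg$maf[1], cfg$maf[2])
      else cfg$maf
    c1 <- (1 - q)^2
    c2 <- c1 + 2 * q * (1 - q)
    u <- matrix(runif(cfg$n_snps * cfg$n_samples), cfg$n_snps)
    idx <- 1L + (u > c1) + (u > c2)
    calls <- matrix(c("AA", "AB", "BB")[idx], cfg$n_snps,
                    dimnames = list(NULL, sprintf("S%04d", seq_len(cfg$n_samples))))
    al <- t(vapply(seq_len(cfg$n_snps),
                   function(i) sample(.nucs, 2), character(2)))
    variants <- tibble(
      rs_id = paste0("rs", seq_len(cfg$n_snps)),
      chrom = as.character(rep(c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19, 21),
                               length.out = cfg$n_snps)),
      pos = as.numeric(seq_len(cfg$n_snps) * 1000),
      allele_major = al[, 1], allele_minor = al[, 2]
    )
    g <- genotype_tbl(variants, calls, platform = "truth")
    attr(g, "maf") <- q
    g
  })
}

#' Observe truth genotypes through a platform's error process
#'
#' Perturbs each true call through the platform's (optionally group-specific
#' and MAF-adjusted) confusion matrix, then masks calls to missing
#' independently at the platform's missing rate. Deterministic under the
#' seed.
#'
#' @param truth A [simulate_truth()] result (calls must be non-missing).
#' @param error_matrix 3x3 row-stochastic confusion matrix.
#' @param missing_rate Per-cell missingness probability.
#' @param seed Stage seed.
#' @param maf_dependence Optional function(maf) -> multiplier on off-diagonal
#'   error mass, applied per SNP (needs the truth's `maf` attribute).
#' @param differential Optional list of matrices named `yes`/`no` replacing
#'   `error_matrix` per sample by phenotype group.
#' @param phenotype Character vector over samples with values `yes`/`no`;
#'   required when `differential` is given.
#' @param platform Label stored on the result.
#' @return A `genotype_tbl` of observed calls.
#' @export
simulate_platform_calls <- function(truth, error_matrix, missing_rate, seed,
                                    maf_dependence = NULL, differential = NULL,
                                    phenotype = NULL, platform = NULL) {
  check_error_matrix(error_matrix)
  tm <- geno_calls(truth)
  if (any(tm == "XX")) abort("truth genotypes must be fully called")
  n_snps <- nrow(tm); n_smp <- ncol(tm)
  t_idx <- matrix(match(tm, gt_levels[1:3]), n_snps)

  if (!is.null(differential)) {
    if (is.null(phenotype)) abort("differential errors need phenotype labels")
    if (length(phenotype) != n_smp || !all(phenotype %in% c("yes", "no"))) {
      abort("`phenotype` must give yes/no per sample")
    }
    lapply(differential, check_error_matrix)
  }

  # per-cell probability rows over the three called classes
  pick_rows <- function(E) E[as.vector(t_idx), , drop = FALSE]
  P <- if (is.null(differential)) pick_rows(error_matrix) else {
    out <- matrix(NA_real_, n_snps * n_smp, 3)
    for (gp in c("yes", "no")) {
      cols <- which(phenotype == gp)
      cells <- as.vector(outer(seq_len(n_snps), (cols - 1) * n_snps, "+"))
      out[cells, ] <- differential[[gp]][as.vector(t_idx[, cols, drop = FALSE]), ]
    }
    out
  }

  if (!is.null(maf_dependence)) {
    q <- attr(truth, "maf")
    if (is.null(q)) abort("`maf_dependence` needs the truth's maf attribute")
    mult <- rep(vapply(q, maf_dependence, numeric(1)), times = n_smp)
    diag_pos <- cbind(seq_len(n_snps * n_smp), as.vector(t_idx))
    d <- P[diag_pos]
    P <- P * mult
    P[diag_pos] <- 1 - mult * (1 - d)
    if (any(P < 0) || any(P > 1)) {
      abort("maf_dependence multiplier pushed confusion probabilities outside [0, 1]")
    }
  }

  withr::with_seed(as.integer(seed), {
    u <- runif(n_snps * n_smp)
    obs <- 1L + (u > P[, 1]) + (u > P[, 1] + P[, 2])
    calls <- matrix(gt_levels[obs], n_snps, dimnames = dimnames(tm))
    if (missing_rate > 0) {
      calls[runif(n_snps * n_smp) < missing_rate] <- "XX"
    }
    set_geno_calls_platform(truth, calls, platform)
  })
}

set_geno_calls_platform <- function(truth, calls, platform) {
  g <- genotype_tbl(geno_variants(truth), calls, platform = platform)
  attr(g, "maf") <- attr(truth, "maf")
  g
}

#' Simulate a phenotype table consistent with its derivation rules
#'
#' Draws binary hypertension and smoking labels at the configured
#' prevalences, then fills in raw per-exam records that round-trip through
#' [derive_hypertension()] / [derive_smoking()]: every hypertensive sample
#' gets at least one exam with systolic pressure above 140 mm Hg or
#' diastolic above 90, every non-hypertensive sample stays at or below both
#' cutoffs at every exam. The sequence source splits samples into directly
#' sequenced (NGS) and imputed at the configured fraction.
#'
#' @param cfg A [sim_config()].
#' @param seed Stage seed; defaults to the second stream of the master seed.
#' @return Phenotype tibble (raw fields plus derived labels), one row per
#'   sample, ids matching [simulate_truth()].
#' @export
simulate_phenotypes <- function(cfg, seed = split_seed(cfg$seed, 4)[2]) {
  n <- cfg$n_samples
  withr::with_seed(as.integer(seed), {
    hyp <- runif(n) < cfg$phenotype_prevalence
    smk <- runif(n) < cfg$smoking_prevalence
    sex <- ifelse(runif(n) < 0.5, "male", "female")

    sbp <- matrix(round(runif(n * 4, 100, 138), 1), n)
    dbp <- matrix(round(runif(n * 4, 60, 88), 1), n)
    hi_exam <- sample.int(4, n, replace = TRUE)
    hi_rows <- which(hyp)
    sbp[cbind(hi_rows, hi_exam[hi_rows])] <- round(runif(length(hi_rows), 142, 185), 1)

    smoke <- matrix(as.numeric(matrix(runif(n * 4), n) < 0.6), n)
    smoke[!smk, ] <- 0
    need <- smk & rowSums(smoke) == 0
    smoke[cbind(which(need), sample.int(4, sum(need), replace = TRUE))] <- 1

    n_ngs <- round(cfg$ngs_fraction * n)
    src <- rep("imputed", n)
    src[sample.int(n, n_ngs)] <- "ngs"

    phen <- tibble(
      id = sprintf("S%04d", seq_len(n)), sex = sex,
      sbp1 = sbp[, 1], sbp2 = sbp[, 2], sbp3 = sbp[, 3], sbp4 = sbp[, 4],
      dbp1 = dbp[, 1], dbp2 = dbp[, 2], dbp3 = dbp[, 3], dbp4 = dbp[, 4],
      smoke1 = smoke[, 1], smoke2 = smoke[, 2], smoke3 = smoke[, 3],
      smoke4 = smoke[, 4],
      sequence_source = src
    )
    derive_phenotypes(phen)
  })
}

#' Simulate a complete paired data set
#'
#' Runs truth, phenotype, and both platform generators under the config's
#' stream-split master seed. When `cfg$differential` is set, the sequence
#' platform's errors follow the per-group matrices keyed to the simulated
#' hypertension labels.
#'
#' @param cfg A [sim_config()].
#' @return List with `truth`, `seq`, `micro` (genotype tables over the same
#'   variants and samples), `phenotypes`, and `config`.
#' @export
simulate_paired_dataset <- function(cfg) {
  seeds <- split_seed(cfg$seed, 4)
  truth <- simulate_truth(cfg, seed = seeds[1])
  phen <- simulate_phenotypes(cfg, seed = seeds[2])
  seq_g <- simulate_platform_calls(
    truth, cfg$error_matrix_seq, cfg$missing_rate_seq, seed = seeds[3],
    maf_dependence = cfg$maf_dependence,
    differential = cfg$differential,
    phenotype = if (!is.null(cfg$differential)) phen$hypertensive,
    platform = "sequence")
  micro_g <- simulate_platform_calls(
    truth, cfg$error_matrix_micro, cfg$missing_rate_micro, seed = seeds[4],
    maf_dependence = cfg$maf_dependence, platform = "microarray")
  list(truth = truth, seq = seq_g, micro = micro_g, phenotypes = phen,
       config = cfg)
}
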