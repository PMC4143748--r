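# Differential-concordance analysis: per-stratum rate summaries and per-cell
# Welch t-tests on per-SNP conditional rates (technology or phenotype groups).

#' Per-stratum conditional-rate summaries
#'
#' Splits the samples by a phenotype stratifier, computes per-SNP conditional
#' rates within each stratum's samples, and summarizes them per cell. With
#' `stratifier = "sequence_source"` this reproduces the NGS-vs-imputed
#' comparison structure (the conditional columns are computed over each
#' source's samples).
#'
#' @param pair A [harmonize()]d pair.
#' @param phen Phenotype table (see [derive_phenotypes()]) with an `id`
#'   column covering the pair's samples; samples with unknown labels are
#'   excluded.
#' @param stratifier One of `"hypertension"`, `"smoking"`, `"sex"`,
#'   `"sequence_source"`.
#' @param weighted Passed to [summarize_rates()].
#' @return Tibble: [summarize_rates()] output with a leading `group` column
#'   (two groups stacked).
#' @export
group_rate_summaries <- function(pair, phen,
                                 stratifier = c("hypertension", "smoking",
                                                "sex", "sequence_source"),
                                 weighted = FALSE) {
  stratifier <- match.arg(stratifier)
  groups <- stratifier_groups(phen, stratifier)
  groups <- lapply(groups, intersect, geno_samples(pair$seq))
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    abort(paste0("stratum with zero samples in the genotype data: ",
                 paste(empty, collapse = ", ")))
  }
  purrr::imap_dfr(groups, function(ids, nm) {
    sm <- summarize_rates(per_snp_conditional_rates(pair, sample_subset = ids),
                          weighted = weighted)
    dplyr::mutate(sm, group = nm, .before = 1)
  })
}

#' Compare average conditional rates between two groups, cell by cell
#'
#' For each of the 16 cells, runs a two-sample t-test on the per-SNP
#' conditional rates of group A versus group B. SNPs lacking a valid
#' denominator (no calls in that microarray column) in either group are
#' dropped from that cell's test; cells where either group retains fewer
#' than 2 SNPs, or both groups have zero variance, are reported undefined
#' (NA statistics). The default is Welch's unequal-variance unpaired test;
#' `paired = TRUE` pairs rates at the same SNP, which is natural for the
#' technology comparison where both groups contribute a rate per SNP.
#'
#' Raw two-sided p-values are reported (no multiplicity correction across
#' the 16 cells); a Bonferroni column is included for convenience, and
#' `p_label` formats values below machine precision as `"< 2.2e-16"`.
#'
#' @inheritParams group_rate_summaries
#' @param paired Pair per-SNP rates across groups instead of Welch unpaired?
#' @return A `group_comparison` tibble: per cell, per-group mean/sd/n plus
#'   `t`, `df`, `p`, `p_bonferroni`, `p_label`; attributes `groups` and
#'   `stratifier`.
#' @export
compare_groups <- function(pair, phen,
                           stratifier = c("hypertension", "smoking",
                                          "sex", "sequence_source"),
                           paired = FALSE) {
  stratifier <- match.arg(stratifier)
  groups <- stratifier_groups(phen, stratifier)
  groups <- lapply(groups, intersect, geno_samples(pair$seq))
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    abort(paste0("stratum with zero samples in the genotype data: ",
                 paste(empty, collapse = ", ")))
  }
  ra <- per_snp_conditional_rates(pair, sample_subset = groups[[1]])
  rb <- per_snp_conditional_rates(pair, sample_subset = groups[[2]])
  cmp <- compare_rate_sets(ra, rb, paired = paired)
  attr(cmp, "groups") <- names(groups)
  attr(cmp, "stratifier") <- stratifier
  cmp
}

# Core per-cell testing on two conditional-rate sets (same SNP universe).
compare_rate_sets <- function(ra, rb, paired = FALSE) {
  key <- c("rs_id", "seq_call", "micro_call")
  j <- dplyr::inner_join(
    dplyr::select(as_tibble(ra), dplyr::all_of(key), rate_a = "rate", valid_a = "valid"),
    dplyr::select(as_tibble(rb), dplyr::all_of(key), rate_b = "rate", valid_b = "valid"),
    by = key)
  j <- dplyr::filter(j, .data$valid_a, .data$valid_b)

  cell_test <- function(d) {
    n_a <- length(d$rate_a); n_b <- length(d$rate_b)
    out <- tibble(
      mean_a = if (n_a > 0) mean(d$rate_a) else NA_real_,
      sd_a = if (n_a > 1) stats::sd(d$rate_a) else NA_real_, n_a = n_a,
      mean_b = if (n_b > 0) mean(d$rate_b) else NA_real_,
      sd_b = if (n_b > 1) stats::sd(d$rate_b) else NA_real_, n_b = n_b,
      t = NA_real_, df = NA_real_, p = NA_real_
    )
    if (n_a < 2 || n_b < 2) return(out)
    if (paired) {
      dd <- d$rate_a - d$rate_b
      if (stats::sd(dd) == 0) {
        if (all(dd == 0)) { out$t <- 0; out$df <- n_a - 1; out$p <- 1 }
        return(out)
      }
      tt <- stats::t.test(d$rate_a, d$rate_b, paired = TRUE)
    } else {
      if (stats::sd(d$rate_a) == 0 && stats::sd(d$rate_b) == 0) {
        if (mean(d$rate_a) == mean(d$rate_b)) { out$t <- 0; out$df <- n_a + n_b - 2; out$p <- 1 }
        return(out)
      }
      tt <- stats::t.test(d$rate_a, d$rate_b, var.equal = FALSE)
    }
    out$t <- unname(tt$statistic); out$df <- unname(tt$parameter)
    out$p <- tt$p.value
    out
  }

  res <- dplyr::group_by(j, .data$seq_call, .data$micro_call)
  res <- dplyr::group_modify(res, function(d, k) cell_test(d))
  res <- dplyr::ungroup(res)
  res <- tidyr::complete(res, .data$seq_call, .data$micro_call)
  res$n_a[is.na(res$n_a)] <- 0L; res$n_b[is.na(res$n_b)] <- 0L
  res$p <- pmax(res$p, .Machine$double.eps)      # floor at machine precision
  res$p_bonferroni <- pmin(res$p * 16, 1)
  res$p_label <- ifelse(is.na(res$p), NA_character_,
                        ifelse(res$p <= .Machine$double.eps, "< 2.2e-16",
                               formatC(res$p, format = "e", digits = 2)))
  tibble::new_tibble(res, class = "group_comparison", paired = paired)
}

#' @describeIn compare_groups The comparison table itself (already tidy).
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) as_tibble(x)

#' @describeIn compare_groups One-row summary: number of testable cells and
#'   significance counts at 0.05 (raw and Bonferroni).
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    stratifier = attr(x, "stratifier") %||% NA_character_,
    group_a = (attr(x, "groups") %||% c(NA, NA))[1],
    group_b = (attr(x, "groups") %||% c(NA, NA))[2],
    n_cells_tested = sum(!is.na(x$p)),
    n_signif_05 = sum(x$p < 0.05, na.rm = TRUE),
    n_signif_bonferroni_05 = sum(x$p_bonferroni < 0.05, na.rm = TRUE),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE))
  )
}

#' @describeIn compare_groups Per-cell -log10 p-value tile plot.
#' @param object A `group_comparison`.
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(as_tibble(object), !is.na(.data$p)),
                  ggplot2::aes(x = .data$micro_call, y = .data$seq_call,
                               fill = -log10(.data$p))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$p_label), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(gt_levels)) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = "microarray call", y = "sequence call",
                  title = "Differential concordance, per cell")
}

#' Write a group-comparison table as TSV
#'
#' Fixed formatting (proportions to 6 significant digits, p-values in
#' scientific notation) so repeated runs diff cleanly.
#'
#' @param cmp A `group_comparison`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(cmp, path) {
  out <- as_tibble(cmp)
  num6 <- function(x) ifelse(is.na(x), NA_character_, formatC(x, format = "g", digits = 6))
  for (cl in c("mean_a", "sd_a", "mean_b", "sd_b", "t", "df")) out[[cl]] <- num6(out[[cl]])
  for (cl in c("p", "p_bonferroni")) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), NA_character_,
                        formatC(out[[cl]], format = "e", digits = 3))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Null-calibration study for the per-cell Welch test
#'
#' Repeatedly simulates paired call sets with nondifferential (phenotype-
#' independent) sequence errors, runs the hypertension comparison, and
#' records the heterozygote-diagonal cell's p-value. Under the null the
#' rejection rate at level `alpha` should sit at `alpha` up to binomial
#' Monte-Carlo error. Each replicate uses 30 SNPs x 100 samples with
#' moderate confusion-matrix errors so per-SNP rates have real variance.
#'
#' @param n_reps Number of independent replicates.
#' @param seed Master seed; per-replicate streams come from [split_seed()].
#' @param alpha Nominal level.
#' @return List with `rejection_rate`, `n_reps`, `p_values`.
#' @export
welch_null_calibration <- function(n_reps = 1000, seed = 1, alpha = 0.05) {
  E <- matrix(c(0.96, 0.03, 0.01,
                0.02, 0.95, 0.03,
                0.01, 0.03, 0.96), 3, 3, byrow = TRUE)
  seeds <- split_seed(seed, n_reps)
  p_values <- vapply(seeds, function(s) {
    cfg <- sim_config(n_snps = 30, n_samples = 100, maf = c(0.2, 0.5),
                      error_matrix_seq = E, error_matrix_micro = diag(3),
                      missing_rate_seq = 0, missing_rate_micro = 0,
                      phenotype_prevalence = 0.5, seed = s)
    sim <- simulate_paired_dataset(cfg)
    pair <- harmonize(sim$seq, sim$micro)
    cmp <- compare_groups(pair, sim$phenotypes, "hypertension")
    cmp$p[cmp$seq_call == "AB" & cmp$micro_call == "AB"]
  }, numeric(1))
  list(rejection_rate = mean(p_values < alpha), n_reps = n_reps,
       p_values = p_values)
}
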