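# Per-SNP conditional concordance rates: for each SNP, the distribution of
# the sequence-platform call conditional on the microarray call, plus
# across-SNP summaries and MAF-stratified versions.

# counts[s, i, j]: number of samples at SNP s with sequence call i and
# microarray call j.
snp_cell_counts <- function(seq_m, micro_m) {
  arr <- array(0, dim = c(nrow(seq_m), 4, 4),
               dimnames = list(rownames(seq_m), gt_levels, gt_levels))
  for (i in 1:4) {
    si <- seq_m == gt_levels[i]
    for (j in 1:4) {
      arr[, i, j] <- rowSums(si & (micro_m == gt_levels[j]))
    }
  }
  arr
}

#' Per-SNP concordance rates conditional on the microarray call
#'
#' For every SNP and every microarray category j with at least one call,
#' computes P(sequence call = i | microarray call = j) as the column's count
#' fractions. Columns with zero denominator are flagged invalid
#' (`valid = FALSE`, rate `NA`) and are excluded from downstream averages
#' rather than erroring.
#'
#' @param pair A [harmonize()]d pair.
#' @param sample_subset Optional sample ids to restrict to (e.g. one
#'   phenotype stratum).
#' @return A `conditional_rates` tibble with one row per SNP x 16 cells:
#'   `rs_id`, `seq_call`, `micro_call`, `count`, `denom`, `rate`, `valid`.
#' @export
per_snp_conditional_rates <- function(pair, sample_subset = NULL) {
  m <- pair_call_matrices(pair, sample_subset)
  arr <- snp_cell_counts(m$seq, m$micro)
  denom <- apply(arr, c(1, 3), sum)          # SNP x micro-column totals
  n_snps <- dim(arr)[1]

  tb <- tibble(
    rs_id = rep(rownames(m$seq), times = 16),
    seq_call = factor(rep(rep(gt_levels, each = n_snps), times = 4),
                      levels = gt_levels),
    micro_call = factor(rep(gt_levels, each = 4 * n_snps), levels = gt_levels),
    count = as.vector(arr),
    denom = as.vector(denom[, rep(1:4, each = 4)])
  )
  tb$valid <- tb$denom > 0
  tb$rate <- ifelse(tb$valid, tb$count / tb$denom, NA_real_)
  tibble::new_tibble(tb, class = "conditional_rates",
                     n_samples = ncol(m$seq))
}

#' Summarize per-SNP conditional rates across SNPs
#'
#' For each of the 16 cells, averages the per-SNP conditional rates over the
#' SNPs whose microarray column has a nonzero denominator. By default each
#' SNP contributes equally (unweighted mean of rates); `weighted = TRUE`
#' instead pools counts across SNPs (count-weighted). Both the across-SNP
#' standard deviation and the standard error of the mean are reported: with
#' hundreds of thousands of SNPs the SE is tiny, so the SD is what describes
#' SNP-to-SNP spread.
#'
#' @param rates A [per_snp_conditional_rates()] result.
#' @param snp_subset Optional rs_ids to restrict to.
#' @param weighted Pool counts across SNPs instead of averaging rates?
#' @return A `rate_summary` tibble: `seq_call`, `micro_call`, `mean`, `sd`,
#'   `se`, `n` (number of SNPs with a valid denominator); cells with n = 0
#'   have NA statistics.
#' @export
summarize_rates <- function(rates, snp_subset = NULL, weighted = FALSE) {
  r <- dplyr::filter(as_tibble(rates), .data$valid)
  if (!is.null(snp_subset)) r <- dplyr::filter(r, .data$rs_id %in% snp_subset)
  grp <- dplyr::group_by(r, .data$seq_call, .data$micro_call)
  if (weighted) {
    sm <- dplyr::summarise(grp,
      mean = sum(.data$count) / sum(.data$denom),
      sd = stats::sd(.data$rate), n = dplyr::n(), .groups = "drop")
  } else {
    sm <- dplyr::summarise(grp,
      mean = mean(.data$rate), sd = stats::sd(.data$rate),
      n = dplyr::n(), .groups = "drop")
  }
  sm$se <- ifelse(sm$n >= 1, sm$sd / sqrt(sm$n), NA_real_)
  full <- tidyr::complete(sm, .data$seq_call, .data$micro_call)
  full$n[is.na(full$n)] <- 0L
  tibble::new_tibble(
    dplyr::select(full, "seq_call", "micro_call", "mean", "sd", "se", "n"),
    class = "rate_summary")
}

#' @describeIn summarize_rates Dot-and-error-bar panel of mean rates per
#'   cell (error bars = across-SNP SD), faceted by microarray call.
#' @param object A `rate_summary`.
#' @param ... Unused.
#' @export
autoplot.rate_summary <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(as_tibble(object), .data$n > 0),
                  ggplot2::aes(x = .data$seq_call, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                        ymax = pmin(.data$mean + .data$sd, 1)),
                           width = 0.2) +
    ggplot2::facet_wrap(~ micro_call, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sequence call", y = "mean conditional rate",
                  title = "Conditional concordance rates (mean ± across-SNP SD)")
}

#' Per-SNP minor allele frequency from called genotypes
#'
#' Counts minor (B) alleles over the called (non-missing) genotypes of one
#' platform: MAF = (n_AB + 2 n_BB) / (2 n_called). SNPs with no called
#' genotypes get NA.
#'
#' @param g A `genotype_tbl`.
#' @return Named numeric vector of MAFs (names = rs_id).
#' @export
snp_maf <- function(g) {
  m <- geno_calls(g)
  n_ab <- rowSums(m == "AB")
  n_bb <- rowSums(m == "BB")
  n_called <- rowSums(m != "XX")
  ifelse(n_called > 0, (n_ab + 2 * n_bb) / (2 * n_called), NA_real_)
}

#' MAF-stratified concordance summaries
#'
#' Assigns each SNP to a MAF bin (half-open intervals from the supplied
#' edges, the last closed at its upper edge; SNPs below the first edge —
#' e.g. monomorphic — fall in the lowest bin) using called genotypes of the
#' chosen platform, then reports per-bin rate summaries and per-bin overall
#' discordance. Lower-MAF SNPs typically show lower cross-platform
#' concordance.
#'
#' @param pair A [harmonize()]d pair.
#' @param bins Increasing numeric vector of bin edges on (0, 0.5]. Default
#'   edges 0.05, 0.1, 0.2, 0.3, 0.4, 0.5.
#' @param maf_source Platform whose calls define the MAF: `"microarray"`
#'   (default) or `"sequence"`.
#' @return A `maf_strata` list: `rates` (per-bin, per-cell [summarize_rates()]
#'   output), `discordance` (per-bin SNP counts and the two overall
#'   discordance proportions), `maf` (per-SNP MAF and bin), `unbinned`
#'   (rs_ids with no called source genotypes, logged and left out).
#' @export
maf_stratified_rates <- function(pair, bins = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                                 maf_source = c("microarray", "sequence")) {
  maf_source <- match.arg(maf_source)
  if (is.unsorted(bins, strictly = TRUE) || length(bins) < 2) {
    abort("`bins` must be strictly increasing edges")
  }
  src <- if (maf_source == "microarray") pair$micro else pair$seq
  maf <- snp_maf(src)

  unbinned <- pair$seq$rs_id[is.na(maf)]
  if (length(unbinned) > 0) {
    inform(sprintf("%d SNP(s) with no called %s genotypes left unbinned",
                   length(unbinned), maf_source))
  }
  idx <- findInterval(maf, bins, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L                    # below lowest edge -> lowest bin
  idx[idx > length(bins) - 1] <- length(bins) - 1L
  labs <- paste0("[", bins[-length(bins)], ",", bins[-1],
                 c(rep(")", length(bins) - 2), "]"))
  bin <- factor(labs[idx], levels = labs)

  maf_tb <- tibble(rs_id = pair$seq$rs_id, maf = maf, bin = bin)
  rates <- per_snp_conditional_rates(pair)

  per_bin <- purrr::map(stats::setNames(labs, labs), function(lb) {
    ids <- maf_tb$rs_id[!is.na(maf_tb$bin) & maf_tb$bin == lb]
    if (length(ids) == 0) return(NULL)
    sm <- summarize_rates(rates, snp_subset = ids)
    tab <- cross_classify(pair, snp_subset = ids)
    list(rates = dplyr::mutate(sm, bin = lb, .before = 1),
         disc = tibble(bin = lb, n_snps = length(ids),
                       called_only = overall_discordance(tab, "called_only"),
                       including_missing = overall_discordance(tab, "including_missing")))
  })
  per_bin <- purrr::compact(per_bin)

  structure(list(
    rates = dplyr::bind_rows(purrr::map(per_bin, "rates")),
    discordance = dplyr::bind_rows(purrr::map(per_bin, "disc")),
    maf = maf_tb,
    unbinned = unbinned
  ), class = "maf_strata")
}

#' @export
print.maf_strata <- function(x, ...) {
  cat("# maf_strata: per-bin overall discordance\n")
  print(x$discordance)
  invisible(x)
}

#' @describeIn maf_stratified_rates Per-bin overall discordance, line plot.
#' @param object A `maf_strata`.
#' @param ... Unused.
#' @export
autoplot.maf_strata <- function(object, ...) {
  d <- tidyr::pivot_longer(object$discordance,
                           c("called_only", "including_missing"),
                           names_to = "mode", values_to = "discordance")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$discordance,
                                  group = .data$mode, colour = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "MAF bin", y = "overall discordance",
                  title = "Discordance by minor allele frequency")
}
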