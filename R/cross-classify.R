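# Pooled 4x4 cross-classification of call pairs. Rows are the sequence-based
# call, columns the microarray call, in the fixed order AA, AB, BB, XX.

#' Cross-classify call pairs over SNPs and samples
#'
#' Counts every (variant, sample) pair of a harmonized call set into one of
#' the 16 categories sequence-call x microarray-call (including missing), in
#' the fixed order AA, AB, BB, XX. The grand total always equals
#' n_snps x n_samples.
#'
#' @param pair A [harmonize()]d pair.
#' @param sample_subset Optional character vector of sample ids to restrict
#'   to (must all be present in the pair).
#' @param snp_subset Optional character vector of rs_ids to restrict to.
#' @return A `cross_class_table`: 16-row tibble with columns `seq_call`,
#'   `micro_call`, `n`, plus attributes `n_snps`, `n_samples`.
#' @export
cross_classify <- function(pair, sample_subset = NULL, snp_subset = NULL) {
  m <- pair_call_matrices(pair, sample_subset, snp_subset)
  tab <- table(factor(m$seq, levels = gt_levels),
               factor(m$micro, levels = gt_levels))
  new_cross_class_table(unclass(tab), n_snps = nrow(m$seq),
                        n_samples = ncol(m$seq))
}

# Shared subsetting for the pooled and per-SNP pathways.
pair_call_matrices <- function(pair, sample_subset = NULL, snp_subset = NULL) {
  cs <- geno_calls(pair$seq)
  cm <- geno_calls(pair$micro)
  if (!is.null(sample_subset)) {
    if (length(sample_subset) == 0) abort("empty sample subset")
    bad <- setdiff(sample_subset, colnames(cs))
    if (length(bad) > 0) abort(paste0("unknown sample(s): ", paste(head(bad, 5), collapse = ", ")))
    cs <- cs[, sample_subset, drop = FALSE]
    cm <- cm[, sample_subset, drop = FALSE]
  }
  if (!is.null(snp_subset)) {
    if (length(snp_subset) == 0) abort("empty SNP subset")
    bad <- setdiff(snp_subset, rownames(cs))
    if (length(bad) > 0) abort(paste0("unknown rs_id(s): ", paste(head(bad, 5), collapse = ", ")))
    cs <- cs[snp_subset, , drop = FALSE]
    cm <- cm[snp_subset, , drop = FALSE]
  }
  list(seq = cs, micro = cm)
}

#' Build a cross-classification table from a 4x4 count matrix
#'
#' Low-level constructor, used by [cross_classify()] and for entering
#' published summary counts.
#'
#' @param counts 4x4 non-negative matrix, rows = sequence call, columns =
#'   microarray call, both ordered AA, AB, BB, XX.
#' @param n_snps,n_samples Dimensions of the underlying paired data set, if
#'   known (grand total = n_snps x n_samples when built over a full pair).
#' @return A `cross_class_table` tibble.
#' @export
new_cross_class_table <- function(counts, n_snps = NA_integer_,
                                  n_samples = NA_integer_) {
  counts <- matrix(as.numeric(counts), 4, 4)
  if (any(counts < 0)) abort("cross-classification counts must be >= 0")
  tb <- tibble(
    seq_call = factor(rep(gt_levels, times = 4), levels = gt_levels),
    micro_call = factor(rep(gt_levels, each = 4), levels = gt_levels),
    n = as.vector(counts)
  )
  tibble::new_tibble(tb, class = "cross_class_table",
                     n_snps = n_snps, n_samples = n_samples)
}

#' Convert a cross-classification table to a 4x4 matrix
#' @param tab A `cross_class_table`.
#' @return Numeric 4x4 matrix, dimnames = genotype categories.
#' @export
crossclass_matrix <- function(tab) {
  matrix(tab$n, 4, 4, dimnames = list(seq = gt_levels, micro = gt_levels))
}

#' @export
print.cross_class_table <- function(x, ...) {
  cat(sprintf("# cross_class_table: %s SNPs x %s samples, %s call pairs\n",
              format(attr(x, "n_snps"), big.mark = ","),
              format(attr(x, "n_samples"), big.mark = ","),
              format(sum(x$n), big.mark = ",")))
  m <- crossclass_matrix(x)
  print(stats::addmargins(as.table(m)))
  invisible(x)
}

#' Overall discordance proportion of a cross-classification table
#'
#' Two conventions are offered, both over the grand total of all 16 cells:
#' `called_only` counts the six off-diagonal cells among called genotypes
#' (AA/AB/BB vs a different AA/AB/BB); `including_missing` additionally
#' counts every pair where exactly one platform's call is missing. Pairs
#' missing on both platforms are treated as concordant-missing under either
#' mode.
#'
#' @param tab A `cross_class_table`.
#' @param mode `"called_only"` or `"including_missing"`.
#' @return Proportion in \[0, 1\].
#' @export
overall_discordance <- function(tab, mode = c("called_only", "including_missing")) {
  mode <- match.arg(mode)
  m <- crossclass_matrix(tab)
  total <- sum(m)
  if (total == 0) abort("cross-classification table has zero total")
  called <- m[1:3, 1:3]
  disc <- sum(called) - sum(diag(called))
  if (mode == "including_missing") {
    one_missing <- sum(m[4, 1:3]) + sum(m[1:3, 4])
    disc <- disc + one_missing
  }
  disc / total
}

#' Break down called discordance by cell
#'
#' Lists the six discordant called-call cells with their counts and their
#' share of all called discordance, largest first — e.g. to identify the
#' dominant discordance classes.
#'
#' @param tab A `cross_class_table`.
#' @return Tibble (seq_call, micro_call, n, share), `share` summing to 1.
#' @export
discordance_breakdown <- function(tab) {
  d <- dplyr::filter(as_tibble(tab),
                     .data$seq_call != .data$micro_call,
                     .data$seq_call != "XX", .data$micro_call != "XX")
  d <- dplyr::arrange(d, dplyr::desc(.data$n))
  dplyr::mutate(d, share = .data$n / sum(.data$n))
}

#' Pooled conditional rates of a cross-classification table
#'
#' Treats the pooled table as a single stratum and divides each cell count
#' by its microarray-column total: entry (i, j) is
#' P(sequence call = i | microarray call = j). Columns with zero total are
#' returned as NA.
#'
#' @param tab A `cross_class_table`.
#' @return 4x4 numeric matrix of conditional proportions; each nonempty
#'   column sums to 1.
#' @export
pooled_conditional_rates <- function(tab) {
  m <- crossclass_matrix(tab)
  cs <- colSums(m)
  sweep(m, 2, ifelse(cs > 0, cs, NA_real_), "/")
}

#' @describeIn cross_classify One-row summary: totals and the two overall
#'   discordance proportions.
#' @param x A `cross_class_table`.
#' @param ... Unused.
#' @export
glance.cross_class_table <- function(x, ...) {
  tibble(
    n_snps = attr(x, "n_snps"), n_samples = attr(x, "n_samples"),
    total_pairs = sum(x$n),
    discordant_called = sum(discordance_breakdown(x)$n),
    discordance_called_only = overall_discordance(x, "called_only"),
    discordance_including_missing = overall_discordance(x, "including_missing")
  )
}

#' Published GAW18 sequence-vs-microarray cross-classification
#'
#' The published pooled cross-classification of genotype calls in the GAW18
#' data: 240,456 SNPs shared between the sequence-based platforms (NGS or
#' MaCH-imputed) and the SNP microarray, over the 959 individuals with data
#' on both, for 230,597,304 call pairs in total. Rows are the sequence call,
#' columns the microarray call. These summary counts are public (the
#' underlying genotypes are access-restricted) and let the headline
#' discordance proportions be recomputed exactly.
#'
#' @return A `cross_class_table`.
#' @examples
#' tab <- gaw18_crossclass()
#' overall_discordance(tab, "including_missing")  # 0.0263
#' overall_discordance(tab, "called_only")        # 0.0023
#' @export
gaw18_crossclass <- function() {
  counts <- matrix(c(
    # micro AA,   micro AB,   micro BB,  micro XX
    117284236,      58271,       1309,      2554,   # seq AA
       101015,   65584521,      29302,      8970,   # seq AB
         6844,     339856,   41656995,     24361,   # seq BB
      3009304,    1506621,     977234,      5911    # seq XX
  ), nrow = 4, byrow = TRUE)
  new_cross_class_table(counts, n_snps = 240456L, n_samples = 959L)
}

#' Write a cross-classification table (with margins) as TSV
#' @param tab A `cross_class_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crossclass_tsv <- function(tab, path) {
  m <- crossclass_matrix(tab)
  out <- as.data.frame(cbind(m, Total = rowSums(m)))
  out <- rbind(out, Total = c(colSums(m), sum(m)))
  out <- cbind(seq_call = c(gt_levels, "Total"), out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @describeIn cross_classify Heat-map of the 16 cell counts (log10 fill).
#' @param object A `cross_class_table`.
#' @export
autoplot.cross_class_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$micro_call, y = .data$seq_call,
                               fill = log10(.data$n + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = format(.data$n, big.mark = ",")),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(gt_levels)) +
    ggplot2::scale_fill_viridis_c(name = "log10 count") +
    ggplot2::labs(x = "microarray call", y = "sequence call",
                  title = "Cross-classification of call pairs")
}
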