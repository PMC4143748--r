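# 50-50 dosage resolution of discordant call pairs. Minor-allele dosages:
# AA = 0, AB = 1, BB = 2. A discordant called pair gets the mean of the two
# dosages, so major-homozygote/heterozygote pairs resolve to 0.5 and
# heterozygote/minor-homozygote pairs to 1.5.

.dosage_map <- c(AA = 0, AB = 1, BB = 2, XX = NA_real_)

#' Resolve one or more call pairs into dosages
#'
#' Equal called pairs keep their dosage (`concordant`); a pair with exactly
#' one missing call uses the available platform's dosage (`one_missing`);
#' both missing gives a missing dosage (`both_missing`); a discordant called
#' pair gets the arithmetic mean of the two dosages
#' (`resolved_discordant`) — 0.5 for major-homozygote/heterozygote pairs,
#' 1.5 for heterozygote/minor-homozygote pairs, and 1.0 for the
#' opposite-homozygote case (an extension of the same mean rule, visible in
#' the provenance). Symmetric in its two arguments.
#'
#' @param g_seq,g_micro Character vectors of calls in `AA`/`AB`/`BB`/`XX`
#'   (recycled to a common length).
#' @return Tibble with `dosage` (in 0, 0.5, 1, 1.5, 2 or NA) and
#'   `provenance` (`concordant`, `one_missing`, `resolved_discordant`,
#'   `both_missing`).
#' @export
resolve_pair <- function(g_seq, g_micro) {
  n <- max(length(g_seq), length(g_micro))
  g_seq <- rep_len(g_seq, n); g_micro <- rep_len(g_micro, n)
  if (!all(c(g_seq, g_micro) %in% gt_levels)) {
    abort("calls must be in AA/AB/BB/XX")
  }
  ds <- unname(.dosage_map[g_seq])
  dm <- unname(.dosage_map[g_micro])
  seq_x <- g_seq == "XX"; mic_x <- g_micro == "XX"

  dosage <- ifelse(seq_x & mic_x, NA_real_,
            ifelse(seq_x, dm,
            ifelse(mic_x, ds, (ds + dm) / 2)))
  provenance <- ifelse(seq_x & mic_x, "both_missing",
                ifelse(seq_x | mic_x, "one_missing",
                ifelse(g_seq == g_micro, "concordant", "resolved_discordant")))
  tibble(dosage = dosage, provenance = provenance)
}

#' Build the resolved dosage matrix for a harmonized pair
#'
#' Applies [resolve_pair()] elementwise over the paired call matrices.
#'
#' @param pair A [harmonize()]d pair.
#' @return A `dosage_tbl`: tibble with the five variant metadata columns and
#'   one numeric dosage column per sample; attributes `provenance`
#'   (character matrix of per-cell provenance codes) and
#'   `provenance_counts` (tibble of code frequencies).
#' @export
build_dosage_matrix <- function(pair) {
  m <- pair_call_matrices(pair)
  res <- resolve_pair(as.vector(m$seq), as.vector(m$micro))
  dim_ <- dim(m$seq); dn <- dimnames(m$seq)
  dos <- matrix(res$dosage, dim_[1], dim_[2], dimnames = dn)
  prov <- matrix(res$provenance, dim_[1], dim_[2], dimnames = dn)

  out <- dplyr::bind_cols(geno_variants(pair$seq),
                          as_tibble(dos, .name_repair = "minimal"))
  out <- tibble::new_tibble(out, class = "dosage_tbl",
                            provenance = prov,
                            provenance_counts = dplyr::count(res, .data$provenance))
  out
}

#' @export
print.dosage_tbl <- function(x, ...) {
  cat(sprintf("# dosage_tbl: %d variants x %d samples\n",
              nrow(x), ncol(x) - length(.geno_meta_cols)))
  pc <- attr(x, "provenance_counts")
  if (!is.null(pc)) {
    cat("# provenance: ",
        paste(sprintf("%s=%d", pc$provenance, pc$n), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Write a dosage matrix as TSV
#'
#' Same layout as the genotype TSV dialect, with numeric dosage cells
#' (missing written as `NA`).
#'
#' @param d A `dosage_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(d, path) {
  readr::write_tsv(as_tibble(as.data.frame(d)), path)
  invisible(path)
}

#' Write a dosage matrix as a minimal VCF with a DS FORMAT field
#'
#' Emits a VCF 4.2 file whose per-sample field is the resolved minor-allele
#' dosage (`DS`); genotype calls are not re-emitted. REF is the major
#' allele, ALT the minor allele of each harmonized variant.
#'
#' @param d A `dosage_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(d, path) {
  smp <- setdiff(names(d), .geno_meta_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Minor-allele dosage resolved from two platforms\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", smp), collapse = "\t")
  ), con)
  vals <- as.matrix(as.data.frame(d)[, smp, drop = FALSE])
  body <- apply(cbind(
    d$chrom, format(d$pos, scientific = FALSE, trim = TRUE), d$rs_id,
    d$allele_major, d$allele_minor, ".", ".", ".", "DS",
    matrix(ifelse(is.na(vals), ".", formatC(vals, format = "g")),
           nrow = nrow(vals))
  ), 1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}
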