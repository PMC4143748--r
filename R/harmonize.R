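# Variant matching and allele harmonization. Variants are matched across
# platforms by rs identifier alone; sites whose allele pairs cannot be
# reconciled are excluded and logged, reproducing the filtering accounting
# matched = retained + excluded.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Match variants between two call sets by rs identifier
#'
#' @param a,b Genotype tables.
#' @return Character vector of rs_ids present in both, ordered as in `a`.
#'   A summary of unmatched counts is attached as attribute `match_summary`.
#'   Errors if the intersection is empty.
#' @export
match_variants <- function(a, b) {
  shared <- a$rs_id[a$rs_id %in% b$rs_id]
  if (length(shared) == 0) {
    abort(sprintf(
      "no shared rs_ids between call sets (%d vs %d variants); check identifiers",
      nrow(a), nrow(b)))
  }
  structure(shared, match_summary = tibble(
    matched = length(shared),
    only_a = nrow(a) - length(shared),
    only_b = nrow(b) - length(shared)
  ))
}

#' Classify the relationship between two platforms' allele pairs
#'
#' For a variant reported by both platforms, compares the (major, minor)
#' allele pairs and classifies how platform b's coding relates to a's:
#' `identical` (same pair, same orientation), `swapped` (major/minor
#' designation reversed), `strand_flip` / `strand_flip_swapped`
#' (Watson-Crick complement, optionally also reversed), `mismatch`
#' (irreconcilable bases), or `ambiguous_palindromic` (A/T or C/G pairs,
#' where a strand flip is indistinguishable from a designation swap).
#'
#' With `allow_strand_flip = FALSE` (the default policy) any relation other
#' than `identical`/`swapped` is reported as `mismatch`, so all sites with
#' differing bases are excluded downstream.
#'
#' @param major_a,minor_a,major_b,minor_b Single-nucleotide allele vectors
#'   (recycled to a common length).
#' @param allow_strand_flip Attempt complement-strand rescue?
#' @return Character vector of classifications.
#' @export
check_allele_consistency <- function(major_a, minor_a, major_b, minor_b,
                                     allow_strand_flip = FALSE) {
  n <- max(length(major_a), length(minor_a), length(major_b), length(minor_b))
  major_a <- rep_len(major_a, n); minor_a <- rep_len(minor_a, n)
  major_b <- rep_len(major_b, n); minor_b <- rep_len(minor_b, n)

  identical_ <- major_a == major_b & minor_a == minor_b
  swapped <- major_a == minor_b & minor_a == major_b
  fa <- unname(.complement[major_a]); fi <- unname(.complement[minor_a])
  flip <- fa == major_b & fi == minor_b
  flip_sw <- fa == minor_b & fi == major_b
  palindromic <- minor_a == unname(.complement[major_a])

  out <- rep("mismatch", n)
  if (allow_strand_flip) {
    out[flip_sw] <- "strand_flip_swapped"
    out[flip] <- "strand_flip"
    out[swapped] <- "swapped"
    out[identical_] <- "identical"
    out[palindromic & (identical_ | swapped | flip | flip_sw)] <- "ambiguous_palindromic"
  } else {
    out[swapped] <- "swapped"
    out[identical_] <- "identical"
  }
  out
}

#' Harmonize two genotype call sets into an analysis-ready pair
#'
#' Restricts both call sets to the shared samples and to the rs-matched,
#' allele-consistent variants, then rewrites the second call set onto the
#' first one's allele orientation: a `swapped` site has its `AA`/`BB` labels
#' exchanged, a `strand_flip` site has its alleles complemented (calls
#' unchanged). Sites classified `mismatch` — and, by default,
#' `ambiguous_palindromic` sites when strand-flip rescue is on — are excluded
#' with a per-site reason, so that retained + excluded = matched always holds.
#'
#' @param seq Genotype table for the sequence-based platform (defines the
#'   reference allele orientation of the result).
#' @param micro Genotype table for the microarray platform.
#' @param allow_strand_flip Rescue complement-strand sites instead of
#'   excluding them? Off by default: any allele-pair difference excludes.
#' @param drop_palindromic With strand-flip rescue on, exclude A/T and C/G
#'   sites (whose orientation is undecidable)? Default `TRUE`.
#' @return A `harmonized_pair`: list with `seq` and `micro` genotype tables
#'   (identical variant and sample order), `orientation` (tibble rs_id,
#'   orientation), `exclusions` (tibble rs_id, reason, a_alleles, b_alleles)
#'   and `log` (named counts for each filtering step).
#' @export
harmonize <- function(seq, micro, allow_strand_flip = FALSE,
                      drop_palindromic = TRUE) {
  validate_genotype_tbl(seq); validate_genotype_tbl(micro)

  shared_smp <- intersect(geno_samples(seq), geno_samples(micro))
  if (length(shared_smp) == 0) abort("no shared samples between the two call sets")
  dropped_smp <- (length(geno_samples(seq)) - length(shared_smp)) +
    (length(geno_samples(micro)) - length(shared_smp))

  matched <- match_variants(seq, micro)
  a <- seq[match(matched, seq$rs_id), , drop = FALSE]
  b <- micro[match(matched, micro$rs_id), , drop = FALSE]

  pos_disagree <- a$chrom != b$chrom | a$pos != b$pos
  if (any(pos_disagree, na.rm = TRUE)) {
    warn(sprintf("%d matched rs_id(s) disagree on chrom/pos between platforms (kept; matching is by rs_id)",
                 sum(pos_disagree, na.rm = TRUE)))
  }

  ori <- check_allele_consistency(a$allele_major, a$allele_minor,
                                  b$allele_major, b$allele_minor,
                                  allow_strand_flip = allow_strand_flip)
  drop <- ori == "mismatch" | (drop_palindromic & ori == "ambiguous_palindromic")
  if (!drop_palindromic) {
    # undecidable orientation treated as identical when the user keeps them
    ori[ori == "ambiguous_palindromic"] <- "identical"
  }

  exclusions <- tibble(
    rs_id = a$rs_id[drop],
    reason = ori[drop],
    a_alleles = paste0(a$allele_major[drop], "/", a$allele_minor[drop]),
    b_alleles = paste0(b$allele_major[drop], "/", b$allele_minor[drop])
  )

  a <- a[!drop, , drop = FALSE]
  b <- b[!drop, , drop = FALSE]
  ori <- ori[!drop]

  ca <- geno_calls(a)[, shared_smp, drop = FALSE]
  cb <- geno_calls(b)[, shared_smp, drop = FALSE]

  sw <- ori %in% c("swapped", "strand_flip_swapped")
  if (any(sw)) cb[sw, ] <- swap_homozygote_labels(cb[sw, , drop = FALSE])

  vb <- geno_variants(b)
  vb$allele_major <- geno_variants(a)$allele_major
  vb$allele_minor <- geno_variants(a)$allele_minor

  pair <- structure(list(
    seq = genotype_tbl(geno_variants(a), ca, platform = "sequence"),
    micro = genotype_tbl(vb, cb, platform = "microarray"),
    orientation = tibble(rs_id = a$rs_id, orientation = ori),
    exclusions = exclusions,
    log = c(matched = length(matched),
            retained = nrow(a),
            excluded = nrow(exclusions),
            shared_samples = length(shared_smp),
            dropped_samples = dropped_smp)
  ), class = "harmonized_pair")
  stopifnot(pair$log[["matched"]] == pair$log[["retained"]] + pair$log[["excluded"]])
  pair
}

# Exchange AA and BB labels (heterozygote and missing untouched).
swap_homozygote_labels <- function(calls) {
  out <- calls
  out[calls == "AA"] <- "BB"
  out[calls == "BB"] <- "AA"
  out
}

#' @export
print.harmonized_pair <- function(x, ...) {
  lg <- x$log
  cat(sprintf(
    "# harmonized_pair: %d variants x %d samples (matched %d, excluded %d)\n",
    lg[["retained"]], lg[["shared_samples"]], lg[["matched"]], lg[["excluded"]]))
  if (nrow(x$exclusions) > 0) {
    cat("# exclusion reasons:\n")
    print(dplyr::count(x$exclusions, .data$reason))
  }
  invisible(x)
}

#' @describeIn harmonize One row per retained variant: rs_id, alleles,
#'   orientation applied to the microarray call set.
#' @param x A `harmonized_pair`.
#' @param ... Unused.
#' @export
tidy.harmonized_pair <- function(x, ...) {
  dplyr::left_join(geno_variants(x$seq), x$orientation, by = "rs_id")
}

#' @describeIn harmonize One-row accounting summary (matched, retained,
#'   excluded, shared samples).
#' @export
glance.harmonized_pair <- function(x, ...) {
  as_tibble(as.list(x$log))
}

#' Write the harmonization exclusion log as TSV
#'
#' @param pair A `harmonized_pair`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(pair, path) {
  readr::write_tsv(pair$exclusions, path)
  invisible(path)
}
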