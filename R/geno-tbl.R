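# Genotype tables: one row per variant, five metadata columns, then one
# column of categorical calls per sample. Calls are coded relative to the
# variant's own (allele_major, allele_minor): AA = two major alleles,
# AB = heterozygote, BB = two minor alleles, XX = missing.

#' Genotype call categories, in fixed table order
#' @export
gt_levels <- c("AA", "AB", "BB", "XX")

.geno_meta_cols <- c("rs_id", "chrom", "pos", "allele_major", "allele_minor")
.nucs <- c("A", "C", "G", "T")

#' Construct a genotype table
#'
#' Builds the package's central container: a tibble with one row per variant,
#' metadata columns `rs_id`, `chrom`, `pos` (1-based), `allele_major`,
#' `allele_minor`, followed by one character column of calls per sample.
#'
#' @param variants Data frame with the five metadata columns.
#' @param calls Character matrix (variants x samples) with values in
#'   `AA`, `AB`, `BB`, `XX`; column names are sample identifiers.
#' @param platform Optional platform label ("sequence" or "microarray"),
#'   stored as an attribute.
#' @return A tibble of class `genotype_tbl`.
#' @export
genotype_tbl <- function(variants, calls, platform = NULL) {
  variants <- as_tibble(variants)[, .geno_meta_cols]
  stopifnot(is.matrix(calls), nrow(calls) == nrow(variants))
  if (is.null(colnames(calls))) {
    abort("`calls` must have sample identifiers as column names.")
  }
  g <- dplyr::bind_cols(variants, as_tibble(calls, .name_repair = "minimal"))
  g <- tibble::new_tibble(g, class = "genotype_tbl", platform = platform)
  validate_genotype_tbl(g)
}

#' Validate a genotype table against its invariants
#'
#' Checks allele and call coding, uniqueness of variant and sample
#' identifiers, and positional sanity. Called by the readers and the
#' constructor; exported so harmonized or hand-built tables can be re-checked.
#'
#' @param g A `genotype_tbl`.
#' @return `g`, invisibly unchanged, or an error describing the violation.
#' @export
validate_genotype_tbl <- function(g) {
  miss <- setdiff(.geno_meta_cols, names(g))
  if (length(miss) > 0) {
    abort(paste0("genotype table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(g$rs_id)) abort("duplicate rs_id in genotype table")
  smp <- geno_samples(g)
  if (length(smp) == 0) abort("genotype table has no sample columns")
  if (anyDuplicated(smp)) abort("duplicate sample identifiers")
  if (any(!is.na(g$pos) & g$pos < 1)) abort("positions must be >= 1")
  bad_al <- !(g$allele_major %in% .nucs) | !(g$allele_minor %in% .nucs) |
    g$allele_major == g$allele_minor
  if (any(bad_al)) {
    abort(paste0("invalid allele pair at rs_id: ",
                 paste(head(g$rs_id[bad_al], 5), collapse = ", ")))
  }
  cm <- geno_calls(g)
  if (!all(cm %in% gt_levels)) {
    bad <- unique(cm[!cm %in% gt_levels])
    abort(paste0("invalid genotype code(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  invisible(g)
}

#' Sample identifiers of a genotype table
#' @param g A `genotype_tbl`.
#' @return Character vector of sample ids, in column order.
#' @export
geno_samples <- function(g) setdiff(names(g), .geno_meta_cols)

#' Extract the call matrix of a genotype table
#' @param g A `genotype_tbl`.
#' @return Character matrix variants x samples, rownames = rs_id.
#' @export
geno_calls <- function(g) {
  smp <- geno_samples(g)
  m <- as.matrix(as.data.frame(g)[, smp, drop = FALSE])
  rownames(m) <- g$rs_id
  m
}

#' Variant metadata of a genotype table
#' @param g A `genotype_tbl`.
#' @return Tibble with the five metadata columns.
#' @export
geno_variants <- function(g) as_tibble(as.data.frame(g)[, .geno_meta_cols])

# Replace the call block, keeping metadata and class.
set_geno_calls <- function(g, calls) {
  genotype_tbl(geno_variants(g), calls, platform = attr(g, "platform"))
}

#' @export
print.genotype_tbl <- function(x, ...) {
  cat(sprintf("# genotype_tbl: %d variants x %d samples%s\n",
              nrow(x), length(geno_samples(x)),
              if (!is.null(attr(x, "platform"))) paste0(" [", attr(x, "platform"), "]") else ""))
  NextMethod()
}

#' Write a genotype table as TSV
#'
#' The dialect is the same one [read_genotypes()] accepts: a header row, five
#' metadata columns (`rs_id`, `chrom`, `pos`, `allele_major`, `allele_minor`;
#' positions 1-based), then one call column per sample with cells in
#' `AA`/`AB`/`BB`/`XX`. Writing and re-reading reproduces the table exactly.
#'
#' @param g A `genotype_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  readr::write_tsv(as_tibble(as.data.frame(g)), path)
  invisible(path)
}
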