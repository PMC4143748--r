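# Readers for the three accepted input dialects. All platform-specific
# missing codes (VCF "./.", PLINK "0 0", TSV "XX"/"NA"/empty) map to XX.
# Variants a reader cannot represent biallelically are dropped and logged in
# the `reader_exclusions` attribute, mirroring the harmonization exclusion log.

#' Read a genotype call set
#'
#' Reads one platform's calls into a [genotype_tbl()] from VCF 4.x (plain or
#' gzip), PLINK text (`.ped`/`.map`) or the package's genotype TSV dialect.
#' Calls are re-encoded relative to each variant's major/minor alleles; for
#' formats that do not state major/minor (VCF, PLINK text) the major allele
#' is the more frequent allele among called genotypes in that file, with ties
#' broken alphabetically. Multiallelic or non-SNP records are excluded with a
#' logged reason (see `attr(, "reader_exclusions")`).
#'
#' @param path Input file. For PLINK text, the `.ped` path or the common
#'   prefix of the `.ped`/`.map` pair.
#' @param format One of `"tsv"`, `"vcf"`, `"plink_text"`.
#' @param platform Optional platform label stored on the result.
#' @return A `genotype_tbl`; excluded records are recorded in the
#'   `reader_exclusions` attribute (tibble of rs_id, reason).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink_text"),
                           platform = NULL) {
  format <- match.arg(format)
  g <- switch(format,
    tsv = read_genotype_tsv(path),
    vcf = read_genotype_vcf(path),
    plink_text = read_genotype_plink(path)
  )
  attr(g, "platform") <- platform
  g
}

read_genotype_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(.geno_meta_cols, hdr)
  if (length(miss) > 0) {
    abort(paste0("TSV ", path, " lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      rs_id = "c", chrom = "c", pos = "d",
      allele_major = "c", allele_minor = "c", .default = "c"
    ), na = character(), progress = FALSE),
    error = function(e) abort(paste0("cannot parse TSV ", path, ": ", conditionMessage(e)))
  )
  miss <- setdiff(.geno_meta_cols, names(df))
  if (length(miss) > 0) {
    abort(paste0("TSV ", path, " lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  smp <- setdiff(names(df), .geno_meta_cols)
  calls <- as.matrix(df[, smp, drop = FALSE])
  calls[calls %in% c("NA", "", ".")] <- "XX"
  g <- genotype_tbl(df[, .geno_meta_cols], calls)
  attr(g, "reader_exclusions") <- tibble(rs_id = character(), reason = character())
  g
}

read_genotype_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse VCF ", path, ": ", conditionMessage(e)))
  )
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort(paste0("VCF ", path, " has no GT field"))

  alt <- fx$ALT %||% rep(NA_character_, nrow(fx))
  biallelic_snp <- !is.na(fx$REF) & !is.na(alt) &
    fx$REF %in% .nucs & alt %in% .nucs
  reason <- rep(NA_character_, nrow(fx))
  reason[grepl(",", alt, fixed = TRUE)] <- "multiallelic"
  reason[is.na(reason) & !biallelic_snp] <- "not_biallelic_snp"
  excl <- tibble(rs_id = fx$ID[!is.na(reason)], reason = reason[!is.na(reason)])

  keep <- is.na(reason)
  if (!any(keep)) abort(paste0("VCF ", path, ": no biallelic SNP records"))
  fx <- fx[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  # ALT-allele count per cell; any "." in the genotype means missing
  strip <- gsub("|", "/", gt, fixed = TRUE)
  nalt <- matrix(NA_integer_, nrow(strip), ncol(strip), dimnames = dimnames(strip))
  called <- !is.na(strip) & !grepl("\\.", strip)
  nalt[called] <- vapply(strsplit(strip[called], "/", fixed = TRUE),
                         function(a) sum(a == "1"), integer(1))

  ids <- fx$ID
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fx$CHROM[no_id], ":", fx$POS[no_id])

  # file-local major allele: more frequent among called genotypes, ties A<C<G<T
  n_called <- rowSums(called)
  alt_frac <- ifelse(n_called > 0, rowSums(nalt, na.rm = TRUE) / (2 * n_called), 0)
  ref_major <- unname(alt_frac < 0.5 | (alt_frac == 0.5 & fx$REF < fx$ALT))

  calls <- matrix("XX", nrow(fx), ncol(nalt), dimnames = list(NULL, colnames(nalt)))
  code_ref_major <- c("AA", "AB", "BB")
  code_alt_major <- c("BB", "AB", "AA")
  for (i in seq_len(nrow(fx))) {
    cd <- if (ref_major[i]) code_ref_major else code_alt_major
    row_called <- called[i, ]
    calls[i, row_called] <- cd[nalt[i, row_called] + 1L]
  }

  variants <- tibble(
    rs_id = ids, chrom = fx$CHROM, pos = as.numeric(fx$POS),
    allele_major = ifelse(ref_major, fx$REF, fx$ALT),
    allele_minor = ifelse(ref_major, fx$ALT, fx$REF)
  )
  g <- genotype_tbl(variants, calls)
  attr(g, "reader_exclusions") <- excl
  g
}

read_genotype_plink <- function(path) {
  ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) abort(paste0("file not found: ", ped_path))
  if (!file.exists(map_path)) abort(paste0("file not found: ", map_path))

  map <- tryCatch(
    utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) abort(paste0("cannot parse .map ", map_path, ": ",
                                     conditionMessage(e)))
  )
  if (ncol(map) < 4) abort(paste0(".map ", map_path, " needs 4 columns (chrom, rs_id, cM, pos)"))
  names(map)[1:4] <- c("chrom", "rs_id", "cm", "pos")

  ped <- tryCatch(
    utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) abort(paste0("cannot parse .ped ", ped_path, ": ",
                                     conditionMessage(e)))
  )
  n_var <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_var) {
    abort(sprintf(".ped %s has %d columns; expected %d for %d variants",
                  ped_path, ncol(ped), 6 + 2 * n_var, n_var))
  }
  samples <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_var) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_var), drop = FALSE])

  calls <- matrix("XX", nrow = n_var, ncol = nrow(ped),
                  dimnames = list(NULL, samples))
  maj <- minr <- rep(NA_character_, n_var)
  reason <- rep(NA_character_, n_var)
  for (j in seq_len(n_var)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0" & x2 != "0"
    als <- sort(unique(c(x1[ok], x2[ok])))
    if (length(als) == 0 || !all(als %in% .nucs)) {
      reason[j] <- "no_valid_alleles"
      next
    }
    if (length(als) > 2) {
      reason[j] <- "more_than_two_alleles"
      next
    }
    cnt <- table(factor(c(x1[ok], x2[ok]), levels = als))
    if (length(als) == 1) {
      # monomorphic in this file: pick any other base as placeholder minor
      maj[j] <- als
      minr[j] <- setdiff(.nucs, als)[1]
    } else {
      # more frequent allele is major; ties alphabetical
      maj[j] <- if (cnt[1] >= cnt[2]) als[1] else als[2]
      minr[j] <- setdiff(als, maj[j])
    }
    n_min <- (x1 == minr[j]) + (x2 == minr[j])
    calls[j, ok] <- c("AA", "AB", "BB")[n_min[ok] + 1L]
  }

  keep <- is.na(reason)
  if (!any(keep)) abort(paste0(ped_path, ": no usable biallelic variants"))
  excl <- tibble(rs_id = map$rs_id[!keep], reason = reason[!keep])
  variants <- tibble(
    rs_id = map$rs_id[keep], chrom = as.character(map$chrom[keep]),
    pos = as.numeric(map$pos[keep]),
    allele_major = maj[keep], allele_minor = minr[keep]
  )
  g <- genotype_tbl(variants, calls[keep, , drop = FALSE])
  attr(g, "reader_exclusions") <- excl
  g
}
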