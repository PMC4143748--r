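# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Genotype table from a call matrix (rows = variants); metadata filled in
# with deterministic defaults unless overridden.
make_geno <- function(calls, rs_id = paste0("rs", seq_len(nrow(calls))),
                      major = rep("A", nrow(calls)),
                      minor = rep("G", nrow(calls)),
                      samples = paste0("S", seq_len(ncol(calls))),
                      platform = NULL) {
  colnames(calls) <- samples
  genotype_tbl(
    tibble::tibble(rs_id = rs_id, chrom = "1",
                   pos = as.numeric(seq_len(nrow(calls)) * 100),
                   allele_major = major, allele_minor = minor),
    calls, platform = platform)
}

# A small harmonized pair straight from two call matrices over identical
# variants (no exclusions).
make_pair <- function(seq_calls, micro_calls, ...) {
  harmonize(make_geno(seq_calls, ...), make_geno(micro_calls, ...))
}

# Random paired call matrices for property tests.
random_pair <- function(n_snps, n_samples, seed) {
  withr::with_seed(seed, {
    draw <- function() matrix(sample(gt_levels, n_snps * n_samples,
                                     replace = TRUE,
                                     prob = c(0.45, 0.3, 0.2, 0.05)),
                              n_snps)
    make_pair(draw(), draw())
  })
}

# Independent brute-force recount: classify every (variant, sample) pair by
# explicit iteration (the oracle the vectorized pathways are checked against).
brute_crossclass <- function(pair) {
  cs <- geno_calls(pair$seq); cm <- geno_calls(pair$micro)
  counts <- matrix(0, 4, 4, dimnames = list(seq = gt_levels, micro = gt_levels))
  for (v in seq_len(nrow(cs))) {
    for (s in seq_len(ncol(cs))) {
      counts[cs[v, s], cm[v, s]] <- counts[cs[v, s], cm[v, s]] + 1
    }
  }
  counts
}

# Brute-force per-SNP conditional rates for one SNP as a plain 4x4 matrix.
brute_conditional <- function(pair, v) {
  cs <- geno_calls(pair$seq); cm <- geno_calls(pair$micro)
  out <- matrix(NA_real_, 4, 4, dimnames = list(gt_levels, gt_levels))
  for (j in gt_levels) {
    idx <- which(cm[v, ] == j)
    if (length(idx) == 0) next
    for (i in gt_levels) out[i, j] <- sum(cs[v, idx] == i) / length(idx)
  }
  out
}

# Exact Monte-Carlo SE of an unweighted mean of per-SNP binomial rates with
# known success probability p0 and per-SNP denominators n_s:
# Var = (1/S^2) * sum p0 (1 - p0) / n_s.
mc_se_unweighted <- function(denoms, p0) {
  denoms <- denoms[denoms > 0]
  sqrt(p0 * (1 - p0) * sum(1 / denoms)) / length(denoms)
}
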