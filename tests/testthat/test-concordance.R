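# Cross-classification, overall discordance, conditional rates, summaries,
# and MAF stratification.

test_that("cross_classify places each pair in exactly one of the 16 cells", {
  pair <- make_pair(matrix(c("AA", "AB"), 1), matrix(c("AA", "BB"), 1))
  tab <- cross_classify(pair)
  m <- crossclass_matrix(tab)
  expect_equal(m["AA", "AA"], 1)
  expect_equal(m["AB", "BB"], 1)
  expect_equal(sum(m), 2)

  # identical matrices put all mass on the diagonal
  calls <- matrix(sample(gt_levels, 20, replace = TRUE), 4)
  pair2 <- make_pair(calls, calls)
  m2 <- crossclass_matrix(cross_classify(pair2))
  expect_equal(sum(diag(m2)), 20)
})

test_that("cross_classify totals are conserved and additive over sample partitions", {
  pair <- random_pair(7, 10, seed = 3)
  full <- cross_classify(pair)
  expect_equal(sum(full$n), 7 * 10)
  smp <- geno_samples(pair$seq)
  part1 <- cross_classify(pair, sample_subset = smp[1:4])
  part2 <- cross_classify(pair, sample_subset = smp[5:10])
  expect_equal(sum(part1$n), 7 * 4)
  expect_equal(part1$n + part2$n, full$n)
  expect_error(cross_classify(pair, sample_subset = character()), "empty")
  expect_error(cross_classify(pair, sample_subset = "nope"), "unknown sample")
})

test_that("cross_classify matches a simulated confusion matrix at Monte-Carlo scale", {
  # 200 SNPs x 500 samples = 1e5 pairs; microarray observes truth exactly,
  # so cell proportions estimate the sequence confusion matrix under HWE
  e <- 0.01
  E <- matrix(c(1 - 2 * e, e, e,
                e, 1 - 2 * e, e,
                e, e, 1 - 2 * e), 3, 3, byrow = TRUE)
  ident <- diag(3)
  cfg <- sim_config(n_snps = 200, n_samples = 500, maf = c(0.2, 0.5),
                    error_matrix_seq = E, error_matrix_micro = ident,
                    missing_rate_seq = 0, missing_rate_micro = 0, seed = 99)
  sim <- simulate_paired_dataset(cfg)
  pair <- harmonize(sim$seq, sim$micro)
  m <- crossclass_matrix(cross_classify(pair))[1:3, 1:3]
  for (j in 1:3) {
    n_j <- sum(m[, j])
    for (i in setdiff(1:3, j)) {
      phat <- m[i, j] / n_j
      se <- sqrt(e * (1 - e) / n_j)
      expect_lt(abs(phat - e), 3 * se + 1e-12)
    }
  }
})

test_that("overall discordance follows the published-table conventions", {
  tab <- gaw18_crossclass()
  expect_equal(sum(tab$n), 230597304)
  expect_equal(round(100 * overall_discordance(tab, "including_missing"), 2), 2.63)
  expect_equal(round(100 * overall_discordance(tab, "called_only"), 2), 0.23)

  diag_only <- new_cross_class_table(diag(c(5, 5, 5, 5)))
  expect_equal(overall_discordance(diag_only, "called_only"), 0)
  expect_equal(overall_discordance(diag_only, "including_missing"), 0)
  expect_error(overall_discordance(new_cross_class_table(matrix(0, 4, 4))), "zero total")
})

test_that("double-missing pairs count as concordant, single-missing as discordant", {
  counts <- matrix(0, 4, 4)
  counts[1, 1] <- 90; counts[4, 4] <- 5; counts[4, 1] <- 3; counts[1, 4] <- 2
  tab <- new_cross_class_table(counts)
  expect_equal(overall_discordance(tab, "called_only"), 0)
  expect_equal(overall_discordance(tab, "including_missing"), 5 / 100)
})

test_that("per-SNP conditional rates divide column counts and flag empty columns", {
  seq_calls <- matrix(c(rep("AA", 9), "AB"), 1)
  micro_calls <- matrix(rep("AA", 10), 1)
  pair <- make_pair(seq_calls, micro_calls)
  r <- per_snp_conditional_rates(pair)
  aa_col <- dplyr::filter(r, micro_call == "AA")
  expect_equal(aa_col$rate[aa_col$seq_call == "AA"], 0.9)
  expect_equal(aa_col$rate[aa_col$seq_call == "AB"], 0.1)
  # no micro BB calls -> BB column invalid, not an error
  bb_col <- dplyr::filter(r, micro_call == "BB")
  expect_true(all(!bb_col$valid))
  expect_true(all(is.na(bb_col$rate)))
})

test_that("valid conditional columns always sum to one", {
  pair <- random_pair(12, 9, seed = 21)
  r <- per_snp_conditional_rates(pair)
  sums <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(r, valid), rs_id, micro_call),
    s = sum(rate), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(r$rate >= 0 & r$rate <= 1, na.rm = TRUE))
})

test_that("statistics agree with a brute-force recount on small fixtures", {
  for (seed in c(5, 6, 7)) {
    pair <- random_pair(5, 5, seed = seed)
    expect_equal(crossclass_matrix(cross_classify(pair)), brute_crossclass(pair))
    r <- per_snp_conditional_rates(pair)
    for (v in seq_len(5)) {
      got <- matrix(NA_real_, 4, 4, dimnames = list(gt_levels, gt_levels))
      rv <- dplyr::filter(r, rs_id == pair$seq$rs_id[v])
      got[cbind(as.character(rv$seq_call), as.character(rv$micro_call))] <- rv$rate
      expect_equal(got, brute_conditional(pair, v))
    }
  }
})

test_that("pooled conditional rates of the published table give the headline entry", {
  pr <- pooled_conditional_rates(gaw18_crossclass())
  expect_equal(pr["AA", "AA"], 117284236 / 120401399)
  expect_equal(round(pr["AA", "AA"], 4), 0.9741)
  expect_true(all(abs(colSums(pr) - 1) < 1e-12))
})

test_that("rate summaries report unweighted mean, across-SNP SD and SE", {
  pair <- make_pair(
    matrix(c("AA", "AA", "AA", "AB", "AA", "AA", "AA", "AA", "AA", "AA"), 2,
           byrow = TRUE),
    matrix("AA", 2, 5))
  sm <- summarize_rates(per_snp_conditional_rates(pair))
  cell <- dplyr::filter(sm, seq_call == "AA", micro_call == "AA")
  # per-SNP rates are 0.8 and 1.0
  expect_equal(cell$mean, 0.9)
  expect_equal(cell$sd, sqrt(((0.8 - 0.9)^2 + (1 - 0.9)^2) / 1))
  expect_equal(cell$se, cell$sd / sqrt(2))
  expect_equal(cell$n, 2L)
  # cells with no valid denominator are reported undefined
  xx <- dplyr::filter(sm, micro_call == "XX")
  expect_true(all(xx$n == 0))
  expect_true(all(is.na(xx$mean)))
})

test_that("identical per-SNP rates give zero spread, and pooling weights by counts", {
  pair <- make_pair(matrix("AA", 3, 4), matrix("AA", 3, 4))
  sm <- summarize_rates(per_snp_conditional_rates(pair))
  cell <- dplyr::filter(sm, seq_call == "AA", micro_call == "AA")
  expect_equal(cell$mean, 1)
  expect_equal(cell$sd, 0)

  # unequal denominators: unweighted vs count-weighted means differ
  seq_calls <- matrix(c("AB", "AA", "AA", "AA",
                        "AA", "AA", "XX", "XX"), 2, byrow = TRUE)
  micro_calls <- matrix(c("AA", "AA", "AA", "AA",
                          "AA", "AA", "XX", "XX"), 2, byrow = TRUE)
  pair2 <- make_pair(seq_calls, micro_calls)
  r2 <- per_snp_conditional_rates(pair2)
  un <- summarize_rates(r2)
  wt <- summarize_rates(r2, weighted = TRUE)
  cell_un <- dplyr::filter(un, seq_call == "AA", micro_call == "AA")$mean
  cell_wt <- dplyr::filter(wt, seq_call == "AA", micro_call == "AA")$mean
  expect_equal(cell_un, (3 / 4 + 1) / 2)
  expect_equal(cell_wt, 5 / 6)
})

test_that("MAF is counted from called genotypes of the chosen source", {
  g <- make_geno(matrix(c("AA", "AA", "AB",
                          "AA", "AA", "AA",
                          "XX", "XX", "XX"), 3, byrow = TRUE))
  maf <- snp_maf(g)
  expect_equal(unname(maf[1]), 1 / 6)
  expect_equal(unname(maf[2]), 0)   # monomorphic
  expect_true(is.na(maf[3]))        # all missing
  expect_named(maf, g$rs_id)
})

test_that("MAF stratification assigns each SNP to one bin and logs unbinnable SNPs", {
  pair <- random_pair(30, 8, seed = 33)
  suppressMessages(ms <- maf_stratified_rates(pair))
  binned <- sum(!is.na(ms$maf$bin))
  expect_equal(binned + length(ms$unbinned), 30)
  expect_equal(sum(ms$discordance$n_snps), binned)
  # monomorphic SNPs go in the lowest bin
  mono <- make_pair(matrix("AA", 2, 4), matrix("AA", 2, 4))
  ms2 <- maf_stratified_rates(mono)
  expect_equal(as.character(unique(ms2$maf$bin)), "[0.05,0.1)")
})

test_that("a MAF-tied error process yields the programmed monotone discordance trend", {
  # off-diagonal error mass scaled by 0.02/MAF: lowest-MAF bins must show
  # the largest discordance, within Monte-Carlo error
  base <- matrix(c(0.98, 0.01, 0.01,
                   0.01, 0.98, 0.01,
                   0.01, 0.01, 0.98), 3, 3, byrow = TRUE)
  cfg <- sim_config(n_snps = 300, n_samples = 400, maf = c(0.05, 0.5),
                    error_matrix_seq = base, error_matrix_micro = diag(3),
                    missing_rate_seq = 0, missing_rate_micro = 0,
                    maf_dependence = function(m) 0.1 / m, seed = 17)
  sim <- simulate_paired_dataset(cfg)
  pair <- harmonize(sim$seq, sim$micro)
  ms <- maf_stratified_rates(pair, bins = c(0.05, 0.15, 0.3, 0.5))
  disc <- ms$discordance$called_only
  # programmed expectation: mean off-diagonal mass 0.02 * (0.1/maf)
  expect_equal(nrow(ms$discordance), 3)
  expect_true(disc[1] > disc[2], info = paste(disc, collapse = " "))
  expect_true(disc[2] > disc[3], info = paste(disc, collapse = " "))
})
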