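# Phenotype derivation, per-group summaries, and Welch comparisons.

test_that("hypertension derivation uses strict thresholds at any exam", {
  expect_equal(derive_hypertension(c(141, 130, NA, NA), c(80, 80, NA, NA)), "yes")
  expect_equal(derive_hypertension(c(140, 140, 140, 140), c(90, 90, 90, 90)), "no")
  expect_equal(derive_hypertension(c(120, 120, 120, 120), c(80, 80, 95, 80)), "yes")
  expect_equal(derive_hypertension(rep(NA_real_, 4), rep(NA_real_, 4)), "unknown")
  expect_error(derive_hypertension(c(-1, 120), c(80, 80)), "positive")
})

test_that("smoking derivation is ever-smoked at any wave", {
  expect_equal(derive_smoking(c(0, 0, 1, NA)), "yes")
  expect_equal(derive_smoking(c(0, 0, 0, 0)), "no")
  expect_equal(derive_smoking(rep(NA_real_, 4)), "unknown")
  expect_error(derive_smoking(c(0, 2)), "0/1")
})

test_that("phenotype TSV round-trips with empty cells as missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("id", "sex", paste0("sbp", 1:4), paste0("dbp", 1:4),
            paste0("smoke", 1:4), "sequence_source"), collapse = "\t"),
    paste(c("P1", "male", "150", "", "", "", "80", "", "", "",
            "0", "1", "", "", "ngs"), collapse = "\t"),
    paste(c("P2", "female", "120", "118", "", "", "70", "72", "", "",
            "0", "0", "0", "0", "imputed"), collapse = "\t")
  ), path)
  phen <- read_phenotypes(path)
  expect_equal(phen$hypertensive, c("yes", "no"))
  expect_equal(phen$smoker, c("yes", "no"))
  expect_true(is.na(phen$sbp2[1]))
})

test_that("group summaries need non-empty strata and exclude unknown labels", {
  pair <- random_pair(6, 6, seed = 2)
  phen <- tibble::tibble(
    id = geno_samples(pair$seq),
    hypertensive = c("yes", "yes", "no", "no", "no", "unknown"),
    sequence_source = "ngs")
  gs <- group_rate_summaries(pair, phen, "hypertension")
  expect_setequal(unique(gs$group), c("hypertensive", "nonhypertensive"))
  phen_one <- dplyr::mutate(phen, hypertensive = "yes")
  expect_error(group_rate_summaries(pair, phen_one, "hypertension"),
               "zero samples")
  expect_error(group_rate_summaries(pair, phen, "sequence_source"),
               "zero samples")
})

test_that("Welch statistic matches the closed-form oracle", {
  # two cells' worth of per-SNP rates, checked against the textbook formula
  x <- c(0.9, 1.0); y <- c(0.5, 0.6)
  sx2 <- var(x); sy2 <- var(y)
  se <- sqrt(sx2 / 2 + sy2 / 2)
  t_oracle <- (mean(x) - mean(y)) / se
  df_oracle <- se^4 / ((sx2 / 2)^2 / 1 + (sy2 / 2)^2 / 1)
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)

  pair <- make_pair(
    matrix(c("AA", "AA", "AA", "AA", "AA", "AA", "AA", "AA", "AA", "AB",
             "AA", "AA", "AA", "AA", "AA", "AB", "AB", "AB", "AB", "AB"),
           2, byrow = TRUE),
    matrix("AA", 2, 10))
  phen <- tibble::tibble(id = geno_samples(pair$seq),
                         hypertensive = rep(c("yes", "no"), each = 5))
  cmp <- compare_groups(pair, phen, "hypertension")
  cell <- dplyr::filter(cmp, seq_call == "AA", micro_call == "AA")
  # group rates: hypertensive {1.0, 0.6}? no - check via the summaries instead
  ra <- per_snp_conditional_rates(pair, sample_subset = phen$id[phen$hypertensive == "yes"])
  rb <- per_snp_conditional_rates(pair, sample_subset = phen$id[phen$hypertensive == "no"])
  xa <- dplyr::filter(ra, seq_call == "AA", micro_call == "AA")$rate
  xb <- dplyr::filter(rb, seq_call == "AA", micro_call == "AA")$rate
  tt <- t.test(xa, xb, var.equal = FALSE)
  expect_equal(cell$t, unname(tt$statistic))
  expect_equal(cell$p, tt$p.value)

  # and the hand-built vectors against the closed form directly
  cmp2 <- genoconcord:::compare_rate_sets(
    tibble::tibble(rs_id = c("rs1", "rs2"), seq_call = factor("AA", gt_levels),
                   micro_call = factor("AA", gt_levels), count = NA, denom = NA,
                   rate = x, valid = TRUE),
    tibble::tibble(rs_id = c("rs1", "rs2"), seq_call = factor("AA", gt_levels),
                   micro_call = factor("AA", gt_levels), count = NA, denom = NA,
                   rate = y, valid = TRUE))
  cell2 <- dplyr::filter(cmp2, seq_call == "AA", micro_call == "AA")
  expect_equal(cell2$t, t_oracle)
  expect_equal(cell2$df, df_oracle)
  expect_equal(cell2$p, p_oracle)
})

test_that("identical rate vectors give t = 0, p = 1 and label swap negates t", {
  pair <- random_pair(8, 10, seed = 4)
  smp <- geno_samples(pair$seq)
  phen <- tibble::tibble(id = smp, hypertensive = rep(c("yes", "no"), each = 5))
  cmp <- compare_groups(pair, phen, "hypertension")
  phen_sw <- dplyr::mutate(phen,
    hypertensive = ifelse(hypertensive == "yes", "no", "yes"))
  cmp_sw <- compare_groups(pair, phen_sw, "hypertension")
  ok <- !is.na(cmp$t) & !is.na(cmp_sw$t)
  expect_true(any(ok))
  expect_equal(cmp$t[ok], -cmp_sw$t[ok])
  expect_equal(cmp$p[ok], cmp_sw$p[ok])

  # degenerate equal-and-constant cell: defined as no evidence of difference
  const <- make_pair(matrix("AA", 3, 6), matrix("AA", 3, 6))
  phen_c <- tibble::tibble(id = geno_samples(const$seq),
                           hypertensive = rep(c("yes", "no"), 3))
  cc <- compare_groups(const, phen_c, "hypertension")
  cell <- dplyr::filter(cc, seq_call == "AA", micro_call == "AA")
  expect_equal(cell$t, 0)
  expect_equal(cell$p, 1)
})

test_that("paired technology comparison uses per-SNP pairing", {
  cfg <- sim_config(n_snps = 40, n_samples = 120, maf = c(0.2, 0.5),
                    missing_rate_seq = 0, missing_rate_micro = 0, seed = 12)
  sim <- simulate_paired_dataset(cfg)
  pair <- harmonize(sim$seq, sim$micro)
  cmp <- compare_groups(pair, sim$phenotypes, "sequence_source", paired = TRUE)
  expect_true(attr(cmp, "paired"))
  cell <- dplyr::filter(cmp, seq_call == "AB", micro_call == "AB")
  expect_true(is.finite(cell$t))
  expect_equal(cell$df, cell$n_a - 1)   # paired df = n - 1
})

test_that("null simulations show no group difference and near-uniform p-values", {
  # nondifferential errors: group means agree within 3 MC SE, and the
  # per-replicate p-values pass a coarse uniformity check
  n_rep <- 200
  p_vals <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    cfg <- sim_config(n_snps = 25, n_samples = 80, maf = c(0.2, 0.5),
                      error_matrix_seq = matrix(c(0.94, 0.03, 0.03,
                                                  0.03, 0.94, 0.03,
                                                  0.03, 0.03, 0.94),
                                                3, 3, byrow = TRUE),
                      error_matrix_micro = diag(3),
                      missing_rate_seq = 0, missing_rate_micro = 0,
                      phenotype_prevalence = 0.5, seed = 1000 + k)
    sim <- simulate_paired_dataset(cfg)
    pair <- harmonize(sim$seq, sim$micro)
    cmp <- compare_groups(pair, sim$phenotypes, "hypertension")
    p_vals[k] <- dplyr::filter(cmp, seq_call == "AB", micro_call == "AB")$p
  }
  ks <- suppressWarnings(ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.001)

  # group means agree: one larger null run
  cfg <- sim_config(n_snps = 300, n_samples = 400, maf = c(0.2, 0.5),
                    missing_rate_seq = 0, missing_rate_micro = 0,
                    phenotype_prevalence = 0.5, seed = 77)
  sim <- simulate_paired_dataset(cfg)
  pair <- harmonize(sim$seq, sim$micro)
  gs <- group_rate_summaries(pair, sim$phenotypes, "hypertension")
  cellwise <- tidyr::pivot_wider(
    dplyr::select(dplyr::filter(gs, seq_call == "AB", micro_call == "AB"),
                  group, mean, se),
    names_from = group, values_from = c(mean, se))
  diff <- abs(cellwise$mean_hypertensive - cellwise$mean_nonhypertensive)
  se <- sqrt(cellwise$se_hypertensive^2 + cellwise$se_nonhypertensive^2)
  expect_lt(diff, 3 * se)
})

test_that("a simulated differential error process is recovered per group", {
  # hypertensive samples carry AB->BB sequence errors at 0.08, others 0.01
  E_no <- matrix(c(0.999, 0.001, 0,
                   0.005, 0.985, 0.01,
                   0, 0.002, 0.998), 3, 3, byrow = TRUE)
  E_yes <- E_no; E_yes[2, 3] <- 0.08; E_yes[2, 2] <- 1 - 0.005 - 0.08
  cfg <- sim_config(n_snps = 400, n_samples = 500, maf = c(0.2, 0.5),
                    error_matrix_micro = diag(3),
                    missing_rate_seq = 0, missing_rate_micro = 0,
                    differential = list(yes = E_yes, no = E_no),
                    phenotype_prevalence = 0.5, seed = 55)
  sim <- simulate_paired_dataset(cfg)
  pair <- harmonize(sim$seq, sim$micro)
  gs <- group_rate_summaries(pair, sim$phenotypes, "hypertension")
  cell <- dplyr::filter(gs, seq_call == "BB", micro_call == "AB")
  got_yes <- cell$mean[cell$group == "hypertensive"]
  got_no <- cell$mean[cell$group == "nonhypertensive"]
  # exact MC SE from the simulator parameters and the realized denominators
  denom_of <- function(gp) {
    ids <- sim$phenotypes$id[sim$phenotypes$hypertensive == gp]
    r <- per_snp_conditional_rates(pair, sample_subset = ids)
    dplyr::filter(r, seq_call == "BB", micro_call == "AB")$denom
  }
  expect_lt(abs(got_yes - 0.08), 3 * mc_se_unweighted(denom_of("yes"), 0.08))
  expect_lt(abs(got_no - 0.01), 3 * mc_se_unweighted(denom_of("no"), 0.01))

  # with this effect size and hundreds of SNPs the affected cell is
  # overwhelmingly significant
  cmp <- compare_groups(pair, sim$phenotypes, "hypertension")
  expect_lt(dplyr::filter(cmp, seq_call == "BB", micro_call == "AB")$p, 1e-6)
})
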