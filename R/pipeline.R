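# End-to-end orchestration: read both call sets and the phenotypes, then
# write the report bundle (pooled cross-classification, conditional-rate
# summaries, group comparisons, MAF strata, exclusions, dosages, run log).

#' Read a pipeline run configuration
#'
#' Configurations are flat YAML key-value files. Recognised keys:
#' `seq_path`, `seq_format`, `micro_path`, `micro_format`, `phenotype_path`,
#' `allow_strand_flip`, `drop_palindromic`, `maf_bins`, `maf_source`,
#' `stratifiers`, `out_dir`, `seed`. Unset keys take the defaults of
#' [run_pipeline()].
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  yaml::read_yaml(path)
}

#' Run the full concordance pipeline and write the report bundle
#'
#' Reads the two call sets and (optionally) the phenotype table, harmonizes,
#' and writes into `out_dir`: `table1_counts.tsv` (pooled 16-cell
#' cross-classification with margins), `table2_conditional_rates.tsv`
#' (across-SNP conditional-rate summaries, overall and per sequence source
#' when available), `table3_group_comparisons_<stratifier>.tsv` (per-cell
#' Welch tests, one file per requested stratifier), `maf_strata.tsv`,
#' `exclusions.tsv`, `dosages.tsv`, and `run_log.txt` with counts at every
#' filtering step. Numeric cells use fixed formatting (6 significant
#' digits; p-values scientific) so reruns diff cleanly.
#'
#' @param config Named list (see [read_run_config()]) or path to a YAML
#'   config file.
#' @return Invisibly, a list of the in-memory results (`pair`, `crossclass`,
#'   `rates_summary`, `comparisons`, `maf`, `dosages`, `log_lines`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  for (k in c("seq_path", "micro_path", "out_dir")) {
    if (is.null(cfg[[k]])) abort(paste0("config key missing: ", k))
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  a <- stage("read_seq", read_genotypes(cfg$seq_path, cfg$seq_format %||% "tsv",
                                        platform = "sequence"))
  b <- stage("read_micro", read_genotypes(cfg$micro_path, cfg$micro_format %||% "tsv",
                                          platform = "microarray"))
  say("read: sequence %d variants x %d samples; microarray %d x %d",
      nrow(a), length(geno_samples(a)), nrow(b), length(geno_samples(b)))

  pair <- stage("harmonize", harmonize(
    a, b, allow_strand_flip = isTRUE(cfg$allow_strand_flip),
    drop_palindromic = cfg$drop_palindromic %||% TRUE))
  lg <- pair$log
  say("harmonize: matched=%d retained=%d excluded=%d shared_samples=%d",
      lg[["matched"]], lg[["retained"]], lg[["excluded"]], lg[["shared_samples"]])
  stopifnot(lg[["matched"]] == lg[["retained"]] + lg[["excluded"]])
  write_exclusion_log(pair, file.path(out_dir, "exclusions.tsv"))

  tab <- stage("cross_classify", cross_classify(pair))
  write_crossclass_tsv(tab, file.path(out_dir, "table1_counts.tsv"))
  say("crossclass: total=%d discordance_called=%s discordance_incl_missing=%s",
      sum(tab$n),
      formatC(overall_discordance(tab, "called_only"), format = "g", digits = 6),
      formatC(overall_discordance(tab, "including_missing"), format = "g", digits = 6))

  phen <- NULL
  if (!is.null(cfg$phenotype_path)) {
    phen <- stage("read_phenotypes", read_phenotypes(cfg$phenotype_path))
    say("phenotypes: %d samples", nrow(phen))
  }

  rates <- stage("conditional_rates", per_snp_conditional_rates(pair))
  summ <- dplyr::mutate(summarize_rates(rates), group = "all", .before = 1)
  if (!is.null(phen) && "sequence_source" %in% names(phen)) {
    summ <- dplyr::bind_rows(
      summ, stage("source_rates",
                  group_rate_summaries(pair, phen, "sequence_source")))
  }
  write_rate_summary_tsv(summ, file.path(out_dir, "table2_conditional_rates.tsv"))

  comparisons <- list()
  strats <- cfg$stratifiers %||% character()
  if (length(strats) > 0 && is.null(phen)) {
    abort("stratifiers requested but no phenotype_path given")
  }
  for (st in strats) {
    cmp <- stage(paste0("compare_", st), compare_groups(pair, phen, st))
    write_comparison_tsv(cmp,
      file.path(out_dir, paste0("table3_group_comparisons_", st, ".tsv")))
    gl <- glance(cmp)
    say("compare %s: %d cells tested, min p = %s", st, gl$n_cells_tested,
        formatC(gl$min_p, format = "e", digits = 2))
    comparisons[[st]] <- cmp
  }

  maf <- stage("maf_strata", maf_stratified_rates(
    pair, bins = cfg$maf_bins %||% c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
    maf_source = cfg$maf_source %||% "microarray"))
  write_maf_strata_tsv(maf, file.path(out_dir, "maf_strata.tsv"))

  dos <- stage("resolve", build_dosage_matrix(pair))
  write_dosage_tsv(dos, file.path(out_dir, "dosages.tsv"))
  pc <- attr(dos, "provenance_counts")
  say("resolve: %s", paste(sprintf("%s=%d", pc$provenance, pc$n), collapse = " "))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(pair = pair, crossclass = tab, rates_summary = summ,
                 comparisons = comparisons, maf = maf, dosages = dos,
                 log_lines = log_lines))
}

#' Write a rate summary as TSV with fixed formatting
#' @param summ A [summarize_rates()] result (optionally with a `group`
#'   column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_summary_tsv <- function(summ, path) {
  out <- as_tibble(summ)
  for (cl in intersect(c("mean", "sd", "se"), names(out))) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), NA_character_,
                        formatC(out[[cl]], format = "g", digits = 6))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write MAF-stratified summaries as TSV
#' @param maf A [maf_stratified_rates()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maf_strata_tsv <- function(maf, path) {
  out <- maf$discordance
  for (cl in c("called_only", "including_missing")) {
    out[[cl]] <- formatC(out[[cl]], format = "g", digits = 6)
  }
  readr::write_tsv(out, path)
  invisible(path)
}
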