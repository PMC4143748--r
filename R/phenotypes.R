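# Phenotype handling: derive binary strata (hypertension from repeated blood
# pressure exams, ever-smoking from repeated waves) from raw per-exam records.

#' Derive hypertension status from repeated blood-pressure exams
#'
#' A subject is hypertensive if at any exam the systolic pressure exceeds
#' 140 mm Hg or the diastolic pressure exceeds 90 mm Hg (strict
#' inequalities); non-hypertensive if every observed exam fails both;
#' unknown if no exam was observed.
#'
#' @param sbp,dbp Systolic / diastolic pressures in mm Hg: numeric vectors
#'   (one subject, up to 4 exams) or matrices (subjects x exams). NA =
#'   exam not observed.
#' @return Character `"yes"`/`"no"`/`"unknown"`, one per subject.
#' @export
derive_hypertension <- function(sbp, dbp) {
  if (!is.matrix(sbp)) sbp <- matrix(sbp, nrow = 1)
  if (!is.matrix(dbp)) dbp <- matrix(dbp, nrow = 1)
  stopifnot(nrow(sbp) == nrow(dbp))
  if (any(sbp <= 0, na.rm = TRUE) || any(dbp <= 0, na.rm = TRUE)) {
    abort("blood pressures must be positive where present")
  }
  high <- (sbp > 140) | (dbp > 90)           # NA-propagating per exam
  any_high <- apply(high, 1, function(x) any(x, na.rm = TRUE))
  none_seen <- rowSums(!is.na(sbp)) + rowSums(!is.na(dbp)) == 0
  ifelse(none_seen, "unknown", ifelse(any_high, "yes", "no"))
}

#' Derive ever-smoking status from repeated survey waves
#'
#' Smoker if self-identified at any wave; non-smoker if every observed wave
#' is 0; unknown if no wave observed.
#'
#' @param smoke Binary (0/1) vector for one subject, up to 4 waves, or a
#'   subjects x waves matrix; NA = not observed.
#' @return Character `"yes"`/`"no"`/`"unknown"`, one per subject.
#' @export
derive_smoking <- function(smoke) {
  if (!is.matrix(smoke)) smoke <- matrix(smoke, nrow = 1)
  if (!all(smoke %in% c(0, 1, NA))) abort("smoking indicators must be 0/1 or NA")
  any_yes <- apply(smoke == 1, 1, function(x) any(x, na.rm = TRUE))
  none_seen <- rowSums(!is.na(smoke)) == 0
  ifelse(none_seen, "unknown", ifelse(any_yes, "yes", "no"))
}

#' Attach derived phenotype strata to a raw phenotype table
#'
#' Takes a per-sample table with columns `id`, `sex`, `sbp1..sbp4`,
#' `dbp1..dbp4`, `smoke1..smoke4`, `sequence_source` and appends the derived
#' `hypertensive` and `smoker` labels, recomputable from the raw exam
#' records via [derive_hypertension()] and [derive_smoking()].
#'
#' @param phen Data frame of raw phenotype records.
#' @return The input as a tibble with `hypertensive` and `smoker` columns.
#' @export
derive_phenotypes <- function(phen) {
  phen <- as_tibble(phen)
  if (!"id" %in% names(phen)) abort("phenotype table needs an `id` column")
  sbp <- as.matrix(phen[, intersect(paste0("sbp", 1:4), names(phen)), drop = FALSE])
  dbp <- as.matrix(phen[, intersect(paste0("dbp", 1:4), names(phen)), drop = FALSE])
  smk <- as.matrix(phen[, intersect(paste0("smoke", 1:4), names(phen)), drop = FALSE])
  if (ncol(sbp) == 0 || ncol(dbp) == 0) abort("phenotype table needs sbp*/dbp* columns")
  phen$hypertensive <- derive_hypertension(sbp, dbp)
  phen$smoker <- if (ncol(smk) > 0) derive_smoking(smk) else "unknown"
  phen
}

#' Read a phenotype table from TSV
#'
#' Expects columns `id`, `sex`, `sbp1..sbp4`, `dbp1..dbp4`,
#' `smoke1..smoke4`, `sequence_source` (values `ngs`/`imputed`); empty
#' cells are missing. Derived strata are attached via [derive_phenotypes()].
#'
#' @param path TSV file path.
#' @return Tibble with raw fields plus `hypertensive` and `smoker`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  phen <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  num_cols <- grep("^(sbp|dbp|smoke)[1-4]$", names(phen), value = TRUE)
  for (cl in num_cols) phen[[cl]] <- as.numeric(phen[[cl]])
  derive_phenotypes(phen)
}

# Resolve a stratifier name to the two sample-id groups it defines.
# Samples with an unknown/missing label are excluded.
stratifier_groups <- function(phen, stratifier) {
  col <- switch(stratifier,
    hypertension = "hypertensive",
    smoking = "smoker",
    sex = "sex",
    sequence_source = "sequence_source",
    abort(paste0("unknown stratifier: ", stratifier))
  )
  if (!col %in% names(phen)) abort(paste0("phenotype table lacks column ", col))
  lab <- phen[[col]]
  keep <- !is.na(lab) & lab != "unknown"
  levels_ <- switch(stratifier,
    hypertension = c("yes", "no"),
    smoking = c("yes", "no"),
    sex = c("male", "female"),
    sequence_source = c("ngs", "imputed")
  )
  groups <- lapply(levels_, function(lv) phen$id[keep & lab == lv])
  names(groups) <- switch(stratifier,
    hypertension = c("hypertensive", "nonhypertensive"),
    smoking = c("smoker", "nonsmoker"),
    sex = c("male", "female"),
    sequence_source = c("ngs", "imputed")
  )
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    abort(paste0("stratum with zero samples: ", paste(empty, collapse = ", ")))
  }
  groups
}
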