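# Phenotype I/O.  One row per subject; booleans are strictly 0/1/empty, and
# optional fields stay explicitly missing (never silently zero).

pheno_bool_cols <- function() {
  c("af_case", "pah", "chf", "chd", "stroke", "diabetes", "dyslipidemia",
    "chronic_resp", "recurred")
}

pheno_num_cols <- function() {
  c("age", "bmi", "duration_months", "age_at_onset", "ef_percent", "lavi")
}

#' Read a phenotype table
#'
#' Expected CSV columns (header required): `subject_id`, `af_case`, `sex`
#' (`male`/`female`), `age` (years), `bmi` (kg/m^2), the comorbidity flags
#' `pah`, `chf`, `chd`, `stroke`, `diabetes`, `dyslipidemia`, `chronic_resp`,
#' and the optional `duration_months` (months since initial AF diagnosis),
#' `age_at_onset` (years), `recurred` (6-month post-cardioversion outcome,
#' defined only for followed cases), `ef_percent` (left ventricular ejection
#' fraction, %), `lavi` (left atrial volume index, mL/m^2).  Booleans must be
#' coded 0/1 (empty = missing); any other coding is an error.  A recurrence
#' outcome on a control is a consistency error.
#'
#' @param path Path to the CSV file.
#' @return A typed tibble, one row per subject.
#' @export
read_phenotypes <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_columns(raw, c("subject_id", "af_case", "sex", "age", "bmi",
                        "pah", "chf", "chd", "stroke", "diabetes",
                        "dyslipidemia", "chronic_resp"), "phenotype file")
  out <- tibble(subject_id = raw$subject_id, sex = tolower(raw$sex))
  for (col in pheno_bool_cols()) {
    out[[col]] <- if (col %in% names(raw)) parse_bool01(raw[[col]], col)
                  else rep(NA, nrow(raw))
  }
  for (col in pheno_num_cols()) {
    out[[col]] <- if (col %in% names(raw)) parse_num(raw[[col]], col)
                  else rep(NA_real_, nrow(raw))
  }
  out <- out[, c("subject_id", "af_case", "sex", "age", "bmi",
                 "pah", "chf", "chd", "stroke", "diabetes", "dyslipidemia",
                 "chronic_resp", "duration_months", "age_at_onset",
                 "recurred", "ef_percent", "lavi")]
  validate_phenotypes(out)
}

validate_phenotypes <- function(pheno) {
  if (anyDuplicated(pheno$subject_id)) {
    abort("subject_id must be unique in the phenotype table",
          class = "afprs_validation_error")
  }
  if (anyNA(pheno$af_case)) {
    abort("af_case is required for every subject", class = "afprs_validation_error")
  }
  bad_sex <- !is.na(pheno$sex) & !pheno$sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort(sprintf("sex must be 'male' or 'female'; found: %s",
                  paste(unique(pheno$sex[bad_sex]), collapse = ", ")),
          class = "afprs_validation_error")
  }
  inconsistent <- !is.na(pheno$recurred) & !pheno$af_case
  if (any(inconsistent)) {
    abort(sprintf("recurrence outcome recorded for control subject(s): %s",
                  paste(pheno$subject_id[inconsistent], collapse = ", ")),
          class = "afprs_consistency_error")
  }
  pheno
}

#' Write a phenotype table to CSV
#'
#' Inverse of [read_phenotypes()]: logicals are written as 0/1, missing
#' values as empty fields.
#'
#' @param pheno A phenotype tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- pheno
  for (col in intersect(pheno_bool_cols(), names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_integer_, as.integer(out[[col]]))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
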