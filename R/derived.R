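# Composite clinical variables used to keep the recurrence models within the
# ten-events-per-variable rule of thumb.

#' CHA2DS2-VASc components available in this data set
#'
#' Scores congestive heart failure (1), age 75+ (2), age 65-74 (1), diabetes
#' (1), prior stroke (2) and female sex (1).  Hypertension and vascular
#' disease are not part of the phenotype dictionary and are not scored.  The
#' dichotomized flag uses the conventional elevated-risk cut: score > 2 for
#' women, > 1 for men (strict inequalities).
#'
#' @param data Phenotype data frame with non-missing `sex`, `age`, `chf`,
#'   `stroke`, `diabetes`.
#' @return `cha2ds2_vasc_score()`: integer scores; `cha2ds2_vasc_flag()`:
#'   logical elevated-risk flags.
#' @export
cha2ds2_vasc_score <- function(data) {
  assert_columns(data, c("sex", "age", "chf", "stroke", "diabetes"), "phenotypes")
  need <- data[, c("sex", "age", "chf", "stroke", "diabetes")]
  if (anyNA(need)) {
    abort("CHA2DS2-VASc needs non-missing sex, age, chf, stroke and diabetes",
          class = "afprs_validation_error")
  }
  as.integer(data$chf + 2L * (data$age >= 75) + (data$age >= 65 & data$age < 75) +
               data$diabetes + 2L * data$stroke + (data$sex == "female"))
}

#' @rdname cha2ds2_vasc_score
#' @export
cha2ds2_vasc_flag <- function(data) {
  score <- cha2ds2_vasc_score(data)
  ifelse(data$sex == "female", score > 2L, score > 1L)
}

#' Combined non-CHA2DS2-VASc comorbidity flag
#'
#' Logical OR of pulmonary arterial hypertension, dyslipidemia, chronic
#' respiratory disease and coronary heart disease.
#'
#' @param data Phenotype data frame with non-missing `pah`, `dyslipidemia`,
#'   `chronic_resp`, `chd`.
#' @return Logical vector.
#' @export
combine_comorbidities <- function(data) {
  assert_columns(data, c("pah", "dyslipidemia", "chronic_resp", "chd"), "phenotypes")
  need <- data[, c("pah", "dyslipidemia", "chronic_resp", "chd")]
  if (anyNA(need)) {
    abort("comorbidity combination needs non-missing pah, dyslipidemia, chronic_resp and chd",
          class = "afprs_validation_error")
  }
  data$pah | data$dyslipidemia | data$chronic_resp | data$chd
}

#' Add derived analysis columns to a phenotype table
#'
#' Adds `male` (indicator), `cha2ds2_flag` and `comorbid_flag` columns used
#' by the multivariate model specifications.
#'
#' @param data Phenotype tibble.
#' @return The tibble with the three extra columns.
#' @export
add_risk_flags <- function(data) {
  data |>
    mutate(male = .data$sex == "male",
           cha2ds2_flag = cha2ds2_vasc_flag(data),
           comorbid_flag = combine_comorbidities(data))
}
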