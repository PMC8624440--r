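# Descriptive group-comparison tables in the layout of the emulated study:
# counts and percentages with an uncorrected chi-squared p for binary
# variables, mean +/- SD with a simple-logistic OR for continuous ones.

descriptive_vars <- function(grouping) {
  switch(grouping,
    case_control = tibble(
      variable = c("male", "age", "bmi", "pah", "chf", "chd", "stroke",
                   "diabetes", "dyslipidemia", "chronic_resp"),
      type = c("binary", "continuous", "continuous", rep("binary", 7))),
    recurrence = tibble(
      variable = c("male", "age", "bmi", "duration_months", "age_at_onset",
                   "pah", "chf", "chd", "stroke", "diabetes", "dyslipidemia",
                   "chronic_resp", "cha2ds2_flag", "comorbid_flag"),
      type = c("binary", rep("continuous", 4), rep("binary", 9))),
    recurrence_echo = tibble(
      variable = c("male", "comorbid_flag", "bmi", "duration_months",
                   "age_at_onset", "lavi", "ef_percent"),
      type = c("binary", "binary", rep("continuous", 5))))
}

#' Descriptive comparison of two outcome groups
#'
#' For `grouping = "case_control"` compares AF cases with controls over the
#' full table; `"recurrence"` compares recurred vs non-recurred among
#' followed cases; `"recurrence_echo"` restricts further to followed cases
#' with echocardiography data.  Binary variables get `n (%)` summaries, a
#' Woolf odds ratio and an uncorrected chi-squared p-value; continuous
#' variables get `mean +/- sd` summaries and a per-unit simple-logistic
#' odds ratio with its Wald p-value.
#'
#' @param phenotypes A phenotype tibble (see [read_phenotypes()]).
#' @param grouping One of `"case_control"`, `"recurrence"`,
#'   `"recurrence_echo"`.
#' @return A tibble with one row per variable: `variable`, `type`, `n1`,
#'   `summary1`, `n2`, `summary2`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   where group 1 is cases (or recurred) and group 2 controls (or
#'   non-recurred).  Group sizes are attached as attribute `group_n`.
#' @export
run_descriptives <- function(phenotypes,
                             grouping = c("case_control", "recurrence",
                                          "recurrence_echo")) {
  grouping <- rlang::arg_match(grouping)
  data <- phenotypes |> mutate(male = .data$sex == "male")
  if (grouping != "case_control") {
    data <- data |>
      filter(!is.na(.data$recurred)) |>
      mutate(cha2ds2_flag = safe_cha2ds2_flag(.data$sex, .data$age, .data$chf,
                                              .data$stroke, .data$diabetes),
             comorbid_flag = .data$pah | .data$dyslipidemia |
               .data$chronic_resp | .data$chd)
    if (grouping == "recurrence_echo") {
      data <- data |> filter(!is.na(.data$ef_percent), !is.na(.data$lavi))
    }
    g <- data$recurred
  } else {
    g <- data$af_case
  }
  if (sum(g) == 0 || sum(!g) == 0) {
    abort(sprintf("descriptives need both outcome groups non-empty (%s)", grouping),
          class = "afprs_validation_error")
  }
  vars <- descriptive_vars(grouping)
  rows <- purrr::pmap(vars, function(variable, type) {
    describe_variable(data, variable, type, g)
  })
  out <- bind_rows(rows)
  attr(out, "group_n") <- c(sum(g), sum(!g))
  attr(out, "grouping") <- grouping
  out
}

describe_variable <- function(data, variable, type, g) {
  x <- data[[variable]]
  base <- tibble(variable = variable, type = type,
                 n1 = sum(g), n2 = sum(!g))
  if (type == "binary") {
    a <- sum(x & g, na.rm = TRUE); b <- sum(!x & g, na.rm = TRUE)
    cc <- sum(x & !g, na.rm = TRUE); d <- sum(!x & !g, na.rm = TRUE)
    res <- tryCatch(two_by_two_or(a, b, cc, d, term = variable),
                    error = function(e) NULL)
    base |> mutate(
      summary1 = sprintf("%d (%.1f)", a, 100 * a / (a + b)),
      summary2 = sprintf("%d (%.1f)", cc, 100 * cc / (cc + d)),
      or = res$or %||% NA_real_, ci_low = res$ci_low %||% NA_real_,
      ci_high = res$ci_high %||% NA_real_, p_value = res$p_value %||% NA_real_)
  } else {
    fit <- tryCatch({
      d <- tibble(.outcome = g, x = x)
      fit_assoc(d, ".outcome", "x", label = variable)
    }, error = function(e) NULL)
    base |> mutate(
      summary1 = sprintf("%.1f ± %.3g", mean(x[g], na.rm = TRUE),
                         stats::sd(x[g], na.rm = TRUE)),
      summary2 = sprintf("%.1f ± %.3g", mean(x[!g], na.rm = TRUE),
                         stats::sd(x[!g], na.rm = TRUE)),
      or = fit$or %||% NA_real_, ci_low = fit$ci_low %||% NA_real_,
      ci_high = fit$ci_high %||% NA_real_, p_value = fit$p_value %||% NA_real_)
  }
}

# NA-propagating CHA2DS2-VASc flag (the exported strict version errors on
# missing inputs; model assembly wants listwise NA handling instead).
safe_cha2ds2_flag <- function(sex, age, chf, stroke, diabetes) {
  score <- chf + 2 * (age >= 75) + (age >= 65 & age < 75) +
    diabetes + 2 * stroke + (sex == "female")
  ifelse(sex == "female", score > 2, score > 1)
}
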