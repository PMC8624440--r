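# Full-study orchestration: descriptive tables, per-SNV occurrence and
# recurrence models, the flip decision, the polygenic score, and the three
# PRS models (occurrence, recurrence, echo subgroup).

model_terms <- function(which) {
  switch(which,
    occurrence = c("age", "male", "bmi", "chf", "chd", "diabetes", "dyslipidemia"),
    recurrence = c("duration_months", "age_at_onset", "cha2ds2_flag", "comorbid_flag"),
    echo = c("ef_percent", "lavi", "male", "bmi", "duration_months",
             "age_at_onset", "comorbid_flag"))
}

#' Run the full occurrence/recurrence PRS study
#'
#' Executes the whole analysis on either a freshly simulated cohort
#' (`config` given) or loaded data (`genotypes` + `phenotypes`, as tibbles
#' or file paths; VCF and CSV dialects as in the I/O functions).  Stages:
#' per-SNV multivariate occurrence models on the full cohort; per-SNV
#' multivariate recurrence models on followed cases; the flip decision (by
#' default from the recurrence models); polygenic score computation and
#' strict dichotomization; and the occurrence-PRS, recurrence-PRS and
#' echo-subgroup models.  The covariate sets of the multivariate models are
#' reconstructions of the emulated study's main-text descriptions and are
#' labelled as such in the report.  A PRS or echo model whose complete-case
#' count cannot support its term count is skipped with a logged notice
#' rather than fitted; per-SNV fits that fail return an NA row flagged
#' `fit_failed`.
#'
#' @param config An [cohort_config()] for simulate mode (exclusive with the
#'   load-mode arguments).
#' @param genotypes,phenotypes Load mode: tibbles, or paths to a VCF/dosage
#'   CSV and a phenotype CSV.
#' @param panel Variant panel (default [af_panel()]); ignored in simulate
#'   mode, where the config's panel is used.
#' @param alpha_flip Flip significance level (default 0.1).
#' @param prs_threshold Strict PRS threshold (default 7).
#' @param missing_policy Missing-genotype policy for [compute_prs()].
#' @param flip_basis Fit set driving the flip decision: `"recurrence"`
#'   (default) or `"occurrence"` (sensitivity analysis).
#' @return An object of class `afprs_study` with elements `descriptives`
#'   (list of tables), `snv_occurrence`, `snv_recurrence` (per-SNV rows),
#'   `flips`, `prs` (per-subject scores and flags joined to outcomes),
#'   `prs_models` (list: `occurrence_prs`, `recurrence_prs`, `echo`),
#'   `notices`, and `provenance`.
#' @export
run_full_study <- function(config = NULL, genotypes = NULL, phenotypes = NULL,
                           panel = NULL, alpha_flip = 0.1, prs_threshold = 7L,
                           missing_policy = "strict",
                           flip_basis = c("recurrence", "occurrence")) {
  flip_basis <- rlang::arg_match(flip_basis)
  simulate_mode <- !is.null(config)
  if (simulate_mode == (!is.null(genotypes) || !is.null(phenotypes))) {
    abort("provide either a config (simulate mode) or genotypes + phenotypes (load mode), not both",
          class = "afprs_validation_error")
  }
  if (simulate_mode) {
    panel <- config$panel
    cohort <- generate_cohort(config)
    genotypes <- cohort$genotypes
    phenotypes <- cohort$phenotypes
    input_hash <- content_hash(unclass(config))
  } else {
    panel <- panel %||% af_panel()
    if (is.character(genotypes)) {
      genotypes <- if (grepl("\\.vcf$", genotypes, ignore.case = TRUE))
        read_genotypes_vcf(genotypes, panel) else read_dosages_csv(genotypes, panel)
    }
    if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
    validate_genotypes(genotypes, panel)
    validate_phenotypes(phenotypes)
    input_hash <- content_hash(list(genotypes, phenotypes, panel))
  }
  notices <- character(0)
  note <- function(msg) {
    notices <<- c(notices, msg)
    inform(paste0("run_full_study: ", msg))
  }

  data <- dplyr::inner_join(phenotypes, genotypes, by = "subject_id")
  if (nrow(data) < nrow(phenotypes)) {
    note(sprintf("%d subject(s) lack genotypes and were dropped",
                 nrow(phenotypes) - nrow(data)))
  }
  data <- data |>
    mutate(male = .data$sex == "male",
           cha2ds2_flag = safe_cha2ds2_flag(.data$sex, .data$age, .data$chf,
                                            .data$stroke, .data$diabetes),
           comorbid_flag = .data$pah | .data$dyslipidemia |
             .data$chronic_resp | .data$chd)
  for (id in panel$snv_id) {
    data[[paste0("carrier_", id)]] <- data[[id]] >= 1L
  }
  followed <- data |> filter(!is.na(.data$recurred))
  echo_set <- followed |> filter(!is.na(.data$ef_percent), !is.na(.data$lavi))

  descriptives <- list(case_control = run_descriptives(data, "case_control"))
  for (grp in c("recurrence", "recurrence_echo")) {
    descriptives[[grp]] <- tryCatch(run_descriptives(data, grp),
      error = function(e) { note(sprintf("descriptives '%s' skipped: %s",
                                         grp, conditionMessage(e))); NULL })
  }

  snv_occurrence <- per_snv_models(data, "af_case", model_terms("occurrence"),
                                   panel, "occurrence (reconstructed covariate set)", note)
  snv_recurrence <- per_snv_models(followed, "recurred", model_terms("recurrence"),
                                   panel, "recurrence (reconstructed covariate set)", note)

  flip_source <- if (flip_basis == "recurrence") snv_recurrence else snv_occurrence
  flips <- decide_flips(flip_source, panel, alpha = alpha_flip)

  prs <- compute_prs(genotypes, panel, flips, missing_policy = missing_policy) |>
    dichotomize(prs_threshold)
  data <- left_join(data, prs[, c("subject_id", "score", "above_threshold")],
                    by = "subject_id") |>
    rename(prs_above = "above_threshold")
  followed <- data |> filter(!is.na(.data$recurred))
  echo_set <- followed |> filter(!is.na(.data$ef_percent), !is.na(.data$lavi))

  prs_models <- list(
    occurrence_prs = gated_fit(data, "af_case",
                               c(model_terms("occurrence"), "prs_above"),
                               "occurrence PRS>threshold (reconstructed covariate set)", note),
    recurrence_prs = gated_fit(followed, "recurred",
                               c(model_terms("recurrence"), "prs_above"),
                               "recurrence PRS>threshold (reconstructed covariate set)", note),
    echo = gated_fit(echo_set, "recurred",
                     c(model_terms("echo"), "prs_above"),
                     "echo subgroup PRS>threshold (reconstructed covariate set)", note))

  report <- list(
    descriptives = descriptives,
    snv_occurrence = snv_occurrence,
    snv_recurrence = snv_recurrence,
    flips = flips,
    prs = data |> select(all_of(c("subject_id", "score", "prs_above",
                                  "af_case", "recurred"))),
    prs_models = prs_models,
    notices = notices)
  report$provenance <- list(
    package_version = as.character(packageVersion("afprs")),
    mode = if (simulate_mode) "simulate" else "load",
    seed = if (simulate_mode) config$seed else NA_integer_,
    alpha_flip = alpha_flip, prs_threshold = prs_threshold,
    missing_policy = missing_policy, flip_basis = flip_basis,
    input_hash = input_hash,
    report_hash = content_hash(report[setdiff(names(report), "notices")]))
  structure(report, class = "afprs_study")
}

# One multivariate model per panel variant; only the carrier term is kept,
# renamed to the variant id.  A failed fit becomes an NA row so the stage
# always completes.
per_snv_models <- function(data, outcome, covariates, panel, label, note) {
  rows <- purrr::map(panel$snv_id, function(id) {
    carrier <- paste0("carrier_", id)
    res <- tryCatch(
      fit_assoc(data, outcome, c(covariates, carrier),
                label = paste(label, id)),
      error = function(e) {
        note(sprintf("per-SNV model %s [%s] failed: %s", id, label,
                     conditionMessage(e)))
        NULL
      })
    if (is.null(res)) {
      tibble(term = id, log_or = NA_real_, or = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, p_value = NA_real_,
             n = sum(complete.cases(data[, c(outcome, covariates, carrier)])),
             model = "multivariate_logistic", warning = "fit_failed")
    } else {
      res |> filter(.data$term == carrier) |> mutate(term = id)
    }
  })
  out <- bind_rows(rows)
  class(out) <- c("afprs_assoc", class(out))
  attr(out, "label") <- label
  out
}

# PRS/echo model stages are fitted only when the complete-case count can
# support the term count; otherwise the stage is skipped with a notice.
gated_fit <- function(data, outcome, terms, label, note) {
  n_complete <- sum(complete.cases(data[, c(outcome, terms)]))
  if (n_complete <= length(terms) + 1) {
    note(sprintf("model '%s' skipped: insufficient complete cases (%d for %d terms)",
                 label, n_complete, length(terms)))
    return(NULL)
  }
  tryCatch(fit_assoc(data, outcome, terms, label = label),
           error = function(e) {
             note(sprintf("model '%s' skipped: %s", label, conditionMessage(e)))
             NULL
           })
}

#' @export
print.afprs_study <- function(x, ...) {
  nn <- attr(x$descriptives$case_control, "group_n")
  cat(sprintf("<afprs_study> %d cases / %d controls\n", nn[1], nn[2]))
  print(x$flips)
  fitted_models <- names(x$prs_models)[!vapply(x$prs_models, is.null, logical(1))]
  cat("PRS models fitted:",
      if (length(fitted_models)) paste(fitted_models, collapse = ", ") else "none", "\n")
  if (length(x$notices)) cat(length(x$notices), "notice(s); see $notices\n")
  invisible(x)
}

#' Forest-plot-ready table from association results
#'
#' Orders the rows as given and marks the variants that the flip rule would
#' re-orient (`p < 0.1` and `OR < 1`).
#'
#' @param results An `afprs_assoc` tibble (non-empty).
#' @return A tibble of class `afprs_forest` with columns `term`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `flip_marker`.
#' @export
render_forest_data <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    abort("no association results to render", class = "afprs_validation_error")
  }
  out <- results |>
    mutate(flip_marker = !is.na(.data$p_value) & !is.na(.data$or) &
             .data$p_value < 0.1 & .data$or < 1) |>
    select(all_of(c("term", "or", "ci_low", "ci_high", "p_value", "flip_marker")))
  class(out) <- c("afprs_forest", class(out))
  out
}
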