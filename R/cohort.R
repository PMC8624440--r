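# Seeded synthetic-cohort generator.  Emulates the statistical structure the
# analysis assumes: Hardy-Weinberg genotypes at the panel frequencies, a
# logistic case/control model over carrier status, covariate marginals drawn
# conditionally on case status, and a logistic recurrence model driven by a
# dichotomized polygenic score and arrhythmia duration.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the package analyses: 259 cases and 108
#' controls; 97 of the cases (37.5%) with a known 6-month post-cardioversion
#' outcome; 50 of those (51.5%) with echocardiography (EF, LAVI).  The only
#' non-null genotype effect on occurrence is a carrier log-OR of log(2.31)
#' for rs2200733; recurrence is driven by PRS>7 (log-OR log(4.174)) and AF
#' duration (log-OR log(1.014) per month), with the intercept calibrated so
#' the expected recurrence fraction among followed cases is 58/97.
#' Covariate means/SDs and prevalences follow the descriptive tables of the
#' emulated study population.
#'
#' @param panel Variant panel tibble (default [af_panel()]).
#' @param n_cases,n_controls Group sizes to fill by rejection sampling.
#' @param beta0_occurrence Log-odds intercept of the occurrence model.
#' @param variant_log_or Named per-variant carrier log-OR vector (occurrence);
#'   names must match `panel$snv_id`.
#' @param covariate_params Nested list of covariate moments/prevalences for
#'   `cases` and `controls`; see the default for the expected shape.
#' @param recurrence_params List with `gamma0` (intercept), `gamma_prs`
#'   (log-OR of PRS > threshold) and `gamma_duration` (log-OR per month).
#' @param followup_fraction Fraction of cases with a recurrence outcome.
#' @param echo_fraction Fraction of followed cases with EF/LAVI.
#' @param prs_threshold Strict score threshold used by the generative
#'   recurrence model (score `> threshold`).
#' @param draw_cap Maximum number of candidate draws before rejection
#'   sampling gives up with a generation error.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   full configuration.
#' @return An object of class `afprs_config`.
#' @export
cohort_config <- function(panel = af_panel(),
                          n_cases = 259L,
                          n_controls = 108L,
                          beta0_occurrence = 0,
                          variant_log_or = NULL,
                          covariate_params = default_covariate_params(),
                          recurrence_params = list(gamma0 = -0.1375,
                                                   gamma_prs = log(4.174),
                                                   gamma_duration = log(1.014)),
                          followup_fraction = 97 / 259,
                          echo_fraction = 50 / 97,
                          prs_threshold = 7L,
                          draw_cap = 1e7,
                          seed = 1L) {
  validate_panel(panel)
  if (is.null(variant_log_or)) {
    variant_log_or <- setNames(rep(0, nrow(panel)), panel$snv_id)
    if ("rs2200733" %in% panel$snv_id) variant_log_or[["rs2200733"]] <- log(2.31)
  }
  if (is.null(names(variant_log_or)) ||
      !setequal(names(variant_log_or), panel$snv_id)) {
    abort("variant_log_or must be a named vector covering every panel variant",
          class = "afprs_validation_error")
  }
  stopifnot(n_cases >= 0, n_controls >= 0,
            followup_fraction >= 0, followup_fraction <= 1,
            echo_fraction >= 0, echo_fraction <= 1, draw_cap >= 1)
  structure(list(panel = panel, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 beta0_occurrence = beta0_occurrence,
                 variant_log_or = variant_log_or[panel$snv_id],
                 covariate_params = covariate_params,
                 recurrence_params = recurrence_params,
                 followup_fraction = followup_fraction,
                 echo_fraction = echo_fraction,
                 prs_threshold = as.integer(prs_threshold),
                 draw_cap = draw_cap, seed = as.integer(seed)),
            class = "afprs_config")
}

#' @rdname cohort_config
#' @export
default_covariate_params <- function() {
  list(
    cases = list(
      age = c(mean = 64.5, sd = 9.77), bmi = c(mean = 31.3, sd = 5.41),
      male = 0.382, pah = 0.776, chf = 0.622, chd = 0.193, stroke = 0.042,
      diabetes = 0.093, dyslipidemia = 0.332, chronic_resp = 0.066,
      duration_months = c(mean = 46, sd = 80),
      age_at_onset = c(mean = 58, sd = 12),
      ef_percent = c(mean = 54, sd = 10), lavi = c(mean = 41, sd = 11)),
    controls = list(
      age = c(mean = 61.4, sd = 9.92), bmi = c(mean = 29.5, sd = 5.44),
      male = 0.361, pah = 0.741, chf = 0.130, chd = 0.028, stroke = 0.074,
      diabetes = 0.185, dyslipidemia = 0.593, chronic_resp = 0.046))
}

#' Sample Hardy-Weinberg genotypes
#'
#' Draws risk-allele dosages independently per variant with genotype
#' probabilities `(1-q)^2`, `2q(1-q)`, `q^2` where `q` is the variant's
#' risk-allele frequency.  No missingness is simulated.
#'
#' @param panel Variant panel tibble.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return A dosage tibble (`subject_id` + one column per variant).
#' @export
sample_genotypes <- function(panel, n, seed = 1L) {
  validate_panel(panel)
  stopifnot(n >= 0)
  with_stream_seed(seed, "genotypes", {
    out <- tibble(subject_id = sprintf("S%05d", seq_len(n)))
    for (k in seq_len(nrow(panel))) {
      out[[panel$snv_id[k]]] <-
        as.integer(rbinom(n, 2L, panel$risk_allele_freq[k]))
    }
    out
  })
}

#' Draw case labels from the logistic occurrence model
#'
#' `P(case) = plogis(beta0 + sum_v log_or_v * carrier_v)` where `carrier_v`
#' is the indicator `dosage >= 1`, matching the carrier coding of the
#' per-SNV regressions the pipeline refits.
#'
#' @param genotypes Dosage tibble aligned with `config$panel`.
#' @param config An `afprs_config`.
#' @param seed Integer seed.
#' @return Logical case labels, one per row of `genotypes`.
#' @export
simulate_occurrence <- function(genotypes, config, seed = config$seed) {
  carriers <- carrier_matrix(genotypes, config$panel)
  eta <- config$beta0_occurrence +
    as.vector(carriers %*% config$variant_log_or)
  with_stream_seed(seed, "occurrence",
                   rbinom(nrow(genotypes), 1L, plogis(eta)) == 1L)
}

carrier_matrix <- function(genotypes, panel) {
  m <- sapply(panel$snv_id, function(id) as.numeric(genotypes[[id]] >= 1L))
  matrix(m, nrow = nrow(genotypes),
         dimnames = list(NULL, panel$snv_id))
}

#' Draw recurrence outcomes for followed cases
#'
#' `P(recur) = plogis(gamma0 + gamma_prs * 1[PRS > threshold] +
#' gamma_duration * duration_months)`.  Only AF cases may receive a
#' recurrence outcome; passing controls is an error.
#'
#' @param cases Phenotype tibble rows for the followed cases (must all have
#'   `af_case = TRUE` and a non-missing `duration_months`).
#' @param prs_above Logical PRS>threshold flag per row of `cases`.
#' @param config An `afprs_config`.
#' @param seed Integer seed.
#' @return Logical recurrence labels.
#' @export
simulate_recurrence <- function(cases, prs_above, config, seed = config$seed) {
  if (any(!cases$af_case)) {
    abort("recurrence can only be simulated for AF cases",
          class = "afprs_validation_error")
  }
  if (length(prs_above) != nrow(cases)) {
    abort("prs_above must have one entry per case", class = "afprs_validation_error")
  }
  rp <- config$recurrence_params
  eta <- rp$gamma0 + rp$gamma_prs * as.numeric(prs_above) +
    rp$gamma_duration * cases$duration_months
  with_stream_seed(seed, "recurrence", rbinom(nrow(cases), 1L, plogis(eta)) == 1L)
}

#' Generate a complete synthetic cohort
#'
#' Composes the genotype, occurrence, covariate, follow-up, recurrence and
#' echocardiography samplers.  Case and control quotas are filled exactly by
#' rejection sampling (error if `draw_cap` candidate draws cannot fill
#' them).  The result is bit-identical for identical configurations; each
#' sampling stage consumes its own random stream derived from the seed, so
#' adding a stage never perturbs earlier draws.
#'
#' @param config An [cohort_config()] object.
#' @return An object of class `afprs_cohort`: a list with `genotypes`,
#'   `phenotypes`, `config` and `true_parameters` (the generating effects,
#'   sufficient to reproduce the cohort).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "afprs_config"))
  panel <- config$panel
  n_total <- config$n_cases + config$n_controls

  case_pool <- list(); control_pool <- list()
  n_case_have <- 0L; n_control_have <- 0L
  draws <- 0; batch_i <- 0L
  batch_n <- max(1000L, n_total)
  while (n_case_have < config$n_cases || n_control_have < config$n_controls) {
    if (draws >= config$draw_cap) {
      abort(sprintf(
        "could not fill %d cases / %d controls within %g draws; occurrence model implies an unattainable prevalence",
        config$n_cases, config$n_controls, config$draw_cap),
        class = "afprs_generation_error")
    }
    batch_i <- batch_i + 1L
    take <- min(batch_n, config$draw_cap - draws)
    g <- with_stream_seed(config$seed, "genotypes", counter = batch_i, {
      out <- tibble(.rows = take)
      for (k in seq_len(nrow(panel))) {
        out[[panel$snv_id[k]]] <-
          as.integer(rbinom(take, 2L, panel$risk_allele_freq[k]))
      }
      out
    })
    lab <- with_stream_seed(config$seed, "occurrence", counter = batch_i, {
      carriers <- carrier_matrix(g, panel)
      eta <- config$beta0_occurrence +
        as.vector(carriers %*% config$variant_log_or)
      rbinom(take, 1L, plogis(eta)) == 1L
    })
    draws <- draws + take
    if (n_case_have < config$n_cases && any(lab)) {
      add <- utils::head(which(lab), config$n_cases - n_case_have)
      case_pool[[length(case_pool) + 1L]] <- g[add, , drop = FALSE]
      n_case_have <- n_case_have + length(add)
    }
    if (n_control_have < config$n_controls && any(!lab)) {
      add <- utils::head(which(!lab), config$n_controls - n_control_have)
      control_pool[[length(control_pool) + 1L]] <- g[add, , drop = FALSE]
      n_control_have <- n_control_have + length(add)
    }
  }
  genotypes <- bind_rows(bind_rows(case_pool), bind_rows(control_pool))
  genotypes <- bind_cols(tibble(subject_id = sprintf("S%05d", seq_len(n_total))),
                         genotypes)
  af_case <- rep(c(TRUE, FALSE), c(config$n_cases, config$n_controls))

  pheno <- with_stream_seed(config$seed, "covariates",
                            draw_covariates(af_case, config$covariate_params))
  pheno <- bind_cols(tibble(subject_id = genotypes$subject_id,
                            af_case = af_case), pheno)

  # Follow-up subset, true PRS flag (raw risk-allele count; the generating
  # flip set is empty), recurrence, then the echo subset.
  n_followed <- round(config$n_cases * config$followup_fraction)
  case_idx <- which(af_case)
  followed_idx <- with_stream_seed(config$seed, "followup",
    sort(case_idx[sample.int(length(case_idx), n_followed)]))
  raw_score <- rowSums(as.matrix(genotypes[, panel$snv_id]))
  prs_above <- raw_score > config$prs_threshold

  pheno$recurred <- NA
  if (n_followed > 0) {
    pheno$recurred[followed_idx] <- simulate_recurrence(
      pheno[followed_idx, ], prs_above[followed_idx], config)
  }

  pheno$ef_percent <- NA_real_; pheno$lavi <- NA_real_
  n_echo <- round(n_followed * config$echo_fraction)
  if (n_echo > 0) {
    echo_idx <- with_stream_seed(config$seed, "echo",
      sort(followed_idx[sample.int(length(followed_idx), n_echo)]))
    cp <- config$covariate_params$cases
    echo_vals <- with_stream_seed(config$seed, "echo", counter = 1L, {
      list(ef = rnorm(n_echo, cp$ef_percent[["mean"]], cp$ef_percent[["sd"]]),
           lavi = rnorm(n_echo, cp$lavi[["mean"]], cp$lavi[["sd"]]))
    })
    pheno$ef_percent[echo_idx] <- echo_vals$ef
    pheno$lavi[echo_idx] <- echo_vals$lavi
  }
  pheno <- validate_phenotypes(pheno[, c("subject_id", "af_case", "sex", "age",
                                         "bmi", "pah", "chf", "chd", "stroke",
                                         "diabetes", "dyslipidemia",
                                         "chronic_resp", "duration_months",
                                         "age_at_onset", "recurred",
                                         "ef_percent", "lavi")])
  structure(list(
    genotypes = genotypes, phenotypes = pheno, config = config,
    true_parameters = list(
      beta0_occurrence = config$beta0_occurrence,
      variant_log_or = config$variant_log_or,
      recurrence_params = config$recurrence_params,
      prs_threshold = config$prs_threshold,
      true_flips = character(0),
      seed = config$seed)),
    class = "afprs_cohort")
}

# Covariates are independent given case status: normal draws for continuous
# variables (log-normal for the right-skewed AF duration), Bernoulli for
# flags.  Duration and onset age exist for cases only.
draw_covariates <- function(af_case, params) {
  n <- length(af_case)
  pheno <- tibble(.rows = n)
  draw_group <- function(p, n) {
    tibble(
      sex = ifelse(runif(n) < p$male, "male", "female"),
      age = rnorm(n, p$age[["mean"]], p$age[["sd"]]),
      bmi = rnorm(n, p$bmi[["mean"]], p$bmi[["sd"]]),
      pah = runif(n) < p$pah, chf = runif(n) < p$chf, chd = runif(n) < p$chd,
      stroke = runif(n) < p$stroke, diabetes = runif(n) < p$diabetes,
      dyslipidemia = runif(n) < p$dyslipidemia,
      chronic_resp = runif(n) < p$chronic_resp,
      duration_months = if (!is.null(p$duration_months))
        rlnorm_mean_sd(n, p$duration_months[["mean"]], p$duration_months[["sd"]])
        else NA_real_,
      age_at_onset = if (!is.null(p$age_at_onset))
        rnorm(n, p$age_at_onset[["mean"]], p$age_at_onset[["sd"]])
        else NA_real_)
  }
  cases <- draw_group(params$cases, sum(af_case))
  controls <- draw_group(params$controls, sum(!af_case))
  out <- tibble(.rows = n)
  for (col in names(cases)) {
    v <- rep(cases[[col]][1], n)
    v[af_case] <- cases[[col]]
    v[!af_case] <- controls[[col]]
    out[[col]] <- v
  }
  out
}

# Log-normal draws parameterized by target mean and SD on the natural scale.
rlnorm_mean_sd <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

#' @export
print.afprs_cohort <- function(x, ...) {
  cat(sprintf("<afprs_cohort> %d cases / %d controls, %d followed, %d with echo\n",
              sum(x$phenotypes$af_case), sum(!x$phenotypes$af_case),
              sum(!is.na(x$phenotypes$recurred)),
              sum(!is.na(x$phenotypes$ef_percent))))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in the same dialects the loaders read: a plain-text VCF
#' of dosages, a phenotype CSV, and a JSON sidecar of the true generating
#' parameters.
#'
#' @param cohort An `afprs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes_vcf(cohort$genotypes, cohort$config$panel,
                      file.path(dir, "genotypes.vcf"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  jsonlite::write_json(cohort$true_parameters,
                       file.path(dir, "true_parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
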