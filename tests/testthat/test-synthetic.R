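test_that("Hardy-Weinberg sampling matches expected dosage moments", {
  panel <- af_panel()
  g <- sample_genotypes(panel, 50000, seed = 101)
  # mean dosage of rs2200733 (q = 0.15) is 2q within 0.01 at this n
  expect_equal(mean(g$rs2200733), 0.30, tolerance = 0.01 / 0.30)
  for (k in seq_len(nrow(panel))) {
    q <- panel$risk_allele_freq[k]
    x <- g[[panel$snv_id[k]]]
    probs <- c(`0` = (1 - q)^2, `1` = 2 * q * (1 - q), `2` = q^2)
    for (dose in 0:2) {
      p_hat <- mean(x == dose)
      p_exp <- probs[[as.character(dose)]]
      se <- sqrt(p_exp * (1 - p_exp) / length(x))
      expect_lt(abs(p_hat - p_exp), 3 * se)
    }
  }
})

test_that("cohort generation is deterministic given the config and seed-sensitive", {
  cfg <- cohort_config(n_cases = 40, n_controls = 20, seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(n_cases = 40, n_controls = 20, seed = 10))
  expect_false(identical(c1$genotypes, c3$genotypes))
})

test_that("a null occurrence model labels about half the draws as cases", {
  panel <- af_panel()
  cfg <- cohort_config(panel = panel, beta0_occurrence = 0,
                       variant_log_or = setNames(rep(0, 8), panel$snv_id),
                       seed = 5)
  g <- sample_genotypes(panel, 10000, seed = 5)
  lab <- simulate_occurrence(g, cfg, seed = 5)
  expect_equal(mean(lab), 0.5, tolerance = 0.02 / 0.5)
})

test_that("unattainable prevalence aborts with a generation error", {
  panel <- af_panel()
  cfg <- cohort_config(panel = panel, n_cases = 100, n_controls = 0,
                       beta0_occurrence = -20,
                       variant_log_or = setNames(rep(0, 8), panel$snv_id),
                       draw_cap = 1e6, seed = 2)
  expect_error(generate_cohort(cfg), class = "afprs_generation_error")
})

test_that("the default configuration reproduces the study's structural counts", {
  cohort <- generate_cohort(cohort_config(seed = 31))
  gl <- glance(cohort)
  expect_equal(gl$n_cases, 259L)
  expect_equal(gl$n_controls, 108L)
  expect_equal(gl$n_followed, 97L)
  expect_equal(gl$n_echo, 50L)
  # case-group age marginal: sample mean within 3 SE of 64.5 (SD 9.77)
  age <- cohort$phenotypes$age[cohort$phenotypes$af_case]
  expect_lt(abs(mean(age) - 64.5), 3 * 9.77 / sqrt(259))
  # duration is positive despite its heavy right skew
  dur <- cohort$phenotypes$duration_months[cohort$phenotypes$af_case]
  expect_true(all(dur > 0))
})

test_that("recurrence marginal matches its intercept when other effects are off", {
  cfg <- cohort_config(n_cases = 5000, n_controls = 0, followup_fraction = 1,
                       echo_fraction = 0,
                       recurrence_params = list(gamma0 = qlogis(0.60),
                                                gamma_prs = 0,
                                                gamma_duration = 0),
                       seed = 77)
  cohort <- generate_cohort(cfg)
  rec <- cohort$phenotypes$recurred
  expect_equal(sum(!is.na(rec)), 5000L)
  expect_equal(mean(rec), 0.60, tolerance = 0.03 / 0.60)
})

test_that("followup_fraction = 0 leaves every recurrence outcome missing", {
  cohort <- generate_cohort(cohort_config(n_cases = 30, n_controls = 10,
                                          followup_fraction = 0, seed = 4))
  expect_true(all(is.na(cohort$phenotypes$recurred)))
})

test_that("recurrence simulation refuses control subjects", {
  cohort <- generate_cohort(cohort_config(n_cases = 10, n_controls = 10, seed = 6))
  expect_error(
    simulate_recurrence(cohort$phenotypes, rep(FALSE, 20), cohort$config),
    class = "afprs_validation_error")
})

test_that("occurrence effects are recovered by refitting across replicates", {
  # single injected carrier log-OR; logistic refit per replicate
  panel <- af_panel()
  truth <- log(2.31)
  n_rep <- 200
  est <- numeric(n_rep)
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(panel = panel, n_cases = 2000, n_controls = 2000,
                         seed = 5000 + r)
    cohort <- generate_cohort(cfg)
    d <- dplyr::inner_join(cohort$phenotypes, cohort$genotypes, "subject_id")
    d$carrier <- d$rs2200733 >= 1
    fit <- fit_assoc(d, "af_case", "carrier")
    est[r] <- fit$log_or
    cover[r] <- fit$ci_low <= exp(truth) && exp(truth) <= fit$ci_high
  }
  expect_lt(abs(mean(est) - truth), 0.05)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
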