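# Univariate and multivariate association machinery: 2x2 odds ratios with
# Woolf (log-normal) confidence intervals, Pearson chi-squared tests without
# continuity correction, logistic model fits with Wald inference, and a
# variance-inflation-factor screen.  This Woolf/uncorrected-chi-squared
# pairing is the one that reproduces the published descriptive tables the
# package targets, so it is used everywhere.

#' Odds ratio of a 2x2 table with a Woolf confidence interval
#'
#' Cells follow the epidemiological convention: `a` exposed cases, `b`
#' unexposed cases, `c` exposed controls, `d` unexposed controls.
#' `OR = ad/bc`; the 95% CI is `exp(log(OR) +/- z * sqrt(1/a+1/b+1/c+1/d))`
#' with `z = qnorm(0.975)`; the p-value is the uncorrected Pearson
#' chi-squared test on the original counts.  If any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied for the OR
#' and CI only, and flagged in the `haldane` column.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param term Optional label for the result row.
#' @return A one-row tibble with columns `term`, `log_or`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `model` (`"two_by_two"`), `haldane`.
#' @examples
#' two_by_two_or(161, 98, 14, 94, term = "chf")
#' @export
two_by_two_or <- function(a, b, c, d, term = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || anyNA(counts)) {
    abort("all four cell counts must be non-negative", class = "afprs_validation_error")
  }
  if (a + b == 0 || c + d == 0) {
    abort("both the case and the control margin must be positive",
          class = "afprs_validation_error")
  }
  haldane <- any(counts == 0)
  cc <- if (haldane) counts + 0.5 else counts
  log_or <- log(cc[["a"]]) - log(cc[["b"]]) - log(cc[["c"]]) + log(cc[["d"]])
  se <- sqrt(sum(1 / cc))
  p <- if (a + c > 0 && b + d > 0) chi2_test(a, b, c, d) else NA_real_
  tibble(term = term, log_or = unname(log_or), or = exp(log_or),
         ci_low = exp(log_or - z975() * se), ci_high = exp(log_or + z975() * se),
         p_value = p, n = sum(counts), model = "two_by_two", haldane = haldane)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson statistic with one
#' degree of freedom.  Both row and both column margins must be positive.
#'
#' @inheritParams two_by_two_or
#' @return The two-sided p-value.
#' @export
chi2_test <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    abort("cell counts must be non-negative", class = "afprs_validation_error")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    abort("chi-squared test needs positive margins", class = "afprs_validation_error")
  }
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  suppressWarnings(chisq.test(m, correct = FALSE))$p.value
}

#' Fit a logistic regression and return per-term Wald results
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]).  Rows with a missing outcome or any missing term are
#' dropped listwise and the dropped count is reported via a message.  Each
#' non-intercept term gets a Wald odds ratio, 95% CI
#' (`exp(beta +/- z * SE)`) and two-sided p-value.  Quasi-complete
#' separation (fitted probabilities at the 0/1 boundary, or a standardized
#' coefficient beyond 15) is flagged in the `warning` column rather than
#' silently reported — small subgroups make this a live concern.
#'
#' @param data A data frame holding the outcome and terms.
#' @param outcome Name of a binary (logical or 0/1) outcome column.
#' @param terms Character vector of predictor column names.
#' @param label Model label stored on the result.
#' @return A tibble of class `afprs_assoc`, one row per estimated term:
#'   `term`, `log_or`, `or`, `ci_low`, `ci_high`, `p_value`, `n`, `model`,
#'   `warning`.
#' @export
fit_assoc <- function(data, outcome, terms, label = NULL) {
  assert_columns(data, c(outcome, terms), "model data")
  if (outcome %in% terms || anyDuplicated(terms)) {
    abort("terms must be unique and must not include the outcome",
          class = "afprs_validation_error")
  }
  cols <- data[, c(outcome, terms)]
  keep <- complete.cases(cols)
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("fit_assoc[%s]: dropped %d row(s) with missing values",
                   label %||% outcome, dropped))
  }
  d <- cols[keep, ]
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1))) {
    abort("outcome must be binary (logical or 0/1)", class = "afprs_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort("outcome is constant after dropping incomplete rows; model is degenerate",
          class = "afprs_fit_error")
  }
  if (nrow(d) <= length(terms)) {
    abort(sprintf("need more complete rows (%d) than model terms (%d)",
                  nrow(d), length(terms)),
          class = "afprs_fit_error")
  }
  d[[outcome]] <- y
  form <- as.formula(paste(outcome, "~", paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- glm(form, family = binomial(), data = d,
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort(sprintf("logistic fit '%s' did not converge", label %||% outcome),
          class = "afprs_fit_error")
  }
  tidy_glm_wald(fit, n = nrow(d), label = label,
                model = if (length(terms) == 1) "simple_logistic"
                        else "multivariate_logistic")
}

# Wald summaries for all non-intercept coefficients of a glm fit, with a
# separation heuristic.  Aliased (rank-deficient) terms come back as NA rows.
tidy_glm_wald <- function(fit, n, label = NULL, model = "multivariate_logistic") {
  beta_all <- coef(fit)
  keep <- names(beta_all) != "(Intercept)"
  beta <- beta_all[keep]
  se <- rep(NA_real_, length(beta))
  est <- !is.na(beta)
  V <- vcov(fit)
  vterms <- intersect(names(beta)[est], rownames(V))
  se[match(vterms, names(beta))] <- sqrt(diag(V)[vterms])

  mm <- model.matrix(fit)
  warn_flag <- rep(NA_character_, length(beta))
  probs <- stats::fitted(fit)
  sep_global <- any(probs < 1e-8 | probs > 1 - 1e-8)
  for (j in seq_along(beta)) {
    if (!est[j]) { warn_flag[j] <- "not_estimable"; next }
    sdx <- stats::sd(mm[, names(beta)[j]])
    std_beta <- if (is.finite(sdx) && sdx > 0) abs(beta[j]) * sdx else abs(beta[j])
    if (sep_global || std_beta > 15) warn_flag[j] <- "possible_separation"
  }
  if (any(warn_flag %in% "possible_separation")) {
    warn(sprintf("model '%s': possible quasi-complete separation", label %||% model))
  }
  res <- tibble(
    term = clean_backticks(names(beta)),
    log_or = unname(beta),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - z975() * se),
    ci_high = exp(unname(beta) + z975() * se),
    p_value = 2 * pnorm(-abs(unname(beta) / se)),
    n = n, model = model, warning = warn_flag)
  class(res) <- c("afprs_assoc", class(res))
  attr(res, "label") <- label
  res
}

clean_backticks <- function(x) {
  x <- gsub("`", "", x)
  sub("TRUE$", "", x)
}

#' Variance inflation factors for a set of model terms
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of term `j` on the remaining terms.  An exactly collinear term
#' yields `Inf`; a constant column is an error.
#'
#' @param data Data frame containing the terms.
#' @param terms Character vector of at least two column names.
#' @return A tibble with columns `term` and `vif`.
#' @export
compute_vif <- function(data, terms) {
  assert_columns(data, terms, "VIF data")
  if (length(terms) < 2) {
    abort("VIF needs at least two terms", class = "afprs_validation_error")
  }
  X <- data[complete.cases(data[, terms]), terms]
  X <- as.data.frame(lapply(X, as.numeric))
  names(X) <- terms
  if (any(vapply(X, function(x) stats::sd(x) == 0, logical(1)))) {
    abort("VIF is undefined for constant columns", class = "afprs_validation_error")
  }
  vif <- vapply(terms, function(tj) {
    # exact collinearity makes lm's summary complain about a perfect fit;
    # that case is legitimate here and reported as +Inf
    r2 <- suppressWarnings(
      summary(lm(X[[tj]] ~ ., data = X[, setdiff(terms, tj), drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = terms, vif = unname(vif))
}
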