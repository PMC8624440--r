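test_that("Woolf odds ratios and CIs reproduce the published tables to 3 decimals", {
  rows <- published_2x2_rows()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    res <- two_by_two_or(r$a, r$b, r$c, r$d, term = r$term)
    expect_equal(round(res$or, 3), r$or, info = r$term)
    expect_equal(round(res$ci_low, 3), r$ci_low, info = r$term)
    expect_equal(round(res$ci_high, 3), r$ci_high, info = r$term)
    expect_false(res$haldane)
  }
})

test_that("a symmetric table gives OR 1 and p 1", {
  res <- two_by_two_or(10, 10, 10, 10)
  expect_equal(res$or, 1)
  expect_equal(res$p_value, 1)
})

test_that("chi-squared test is the uncorrected Pearson statistic", {
  # equal proportions: statistic 0, p 1
  expect_equal(chi2_test(20, 80, 10, 40), 1)
  # congestive heart failure row is overwhelmingly significant
  expect_lt(chi2_test(161, 98, 14, 94), 0.001)
  # brute-force oracle: sum (O-E)^2/E against pchisq, on the stroke row
  counts <- c(a = 3, b = 55, c = 2, d = 37)
  O <- matrix(counts, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  p_oracle <- pchisq(sum((O - E)^2 / E), df = 1, lower.tail = FALSE)
  expect_equal(chi2_test(3, 55, 2, 37), p_oracle)
  expect_equal(round(p_oracle, 3), 0.992)
})

test_that("degenerate tables are rejected and zero cells trigger Haldane-Anscombe", {
  expect_error(two_by_two_or(0, 0, 5, 5), class = "afprs_validation_error")
  expect_error(chi2_test(0, 10, 0, 10), class = "afprs_validation_error")
  res <- two_by_two_or(30, 0, 15, 5)
  expect_true(res$haldane)
  expect_true(is.finite(res$or))
  # oracle: +0.5 on every cell
  expect_equal(res$or, (30.5 * 5.5) / (0.5 * 15.5))
})

test_that("adding exposed cases strictly increases the odds ratio", {
  set.seed(42)
  for (i in 1:20) {
    t0 <- sample(1:50, 4)
    k <- sample(1:10, 1)
    or0 <- two_by_two_or(t0[1], t0[2], t0[3], t0[4])$or
    or1 <- two_by_two_or(t0[1] + k, t0[2], t0[3], t0[4])$or
    expect_gt(or1, or0)
  }
})

test_that("logistic regression on one binary predictor equals the cross-product OR", {
  set.seed(7)
  for (i in 1:10) {
    tt <- sample(3:80, 4)
    d <- table_to_data(tt[1], tt[2], tt[3], tt[4])
    fit <- fit_assoc(d, "y", "x")
    or_2x2 <- two_by_two_or(tt[1], tt[2], tt[3], tt[4])$or
    expect_equal(fit$or, or_2x2, tolerance = 1e-6)
  }
  # the headline heart-failure row, to the printed precision
  d <- table_to_data(161, 98, 14, 94)
  expect_equal(round(fit_assoc(d, "y", "x")$or, 3), 11.031)
})

test_that("logistic fits recover a known effect and reject degenerate outcomes", {
  set.seed(88)
  n <- 4000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  fit <- fit_assoc(tibble::tibble(y = y, x = x), "y", "x")
  se <- (log(fit$ci_high) - log(fit$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(fit$log_or - 0.8), 3 * se)
  expect_error(fit_assoc(tibble::tibble(y = rep(1, 20), x = rnorm(20)), "y", "x"),
               class = "afprs_fit_error")
})

test_that("missing rows are dropped listwise with a message", {
  d <- tibble::tibble(y = rep(c(0, 1), 25), x = rnorm(50), z = rnorm(50))
  d$x[1:5] <- NA
  expect_message(fit <- fit_assoc(d, "y", c("x", "z")), "dropped 5")
  expect_equal(unique(fit$n), 45L)
})

test_that("variance inflation factors behave as the closed form predicts", {
  set.seed(3)
  n <- 10000
  x1 <- rnorm(n); x2 <- rnorm(n)
  v <- compute_vif(tibble::tibble(x1 = x1, x2 = x2), c("x1", "x2"))
  expect_equal(v$vif, c(1, 1), tolerance = 0.05)

  # near-collinear pair engineered for R^2 = 0.9
  x3 <- x1 + rnorm(n, sd = 1 / 3)
  v3 <- compute_vif(tibble::tibble(x1 = x1, x3 = x3), c("x1", "x3"))
  r2 <- summary(lm(x3 ~ x1))$r.squared
  expect_equal(v3$vif[v3$term == "x3"], 1 / (1 - r2), tolerance = 1e-10)
  expect_equal(v3$vif[v3$term == "x3"], 10, tolerance = 0.08)

  # exact duplicates explode; constants are rejected
  vd <- compute_vif(tibble::tibble(a = x1, b = x1), c("a", "b"))
  expect_true(all(is.infinite(vd$vif)))
  expect_error(compute_vif(tibble::tibble(a = x1, b = rep(1, n)), c("a", "b")),
               class = "afprs_validation_error")
})

test_that("CHA2DS2-VASc scoring uses the available components with strict cuts", {
  row <- function(sex, age, chf = FALSE, stroke = FALSE, diabetes = FALSE) {
    tibble::tibble(sex = sex, age = age, chf = chf, stroke = stroke,
                   diabetes = diabetes)
  }
  expect_equal(cha2ds2_vasc_score(row("male", 70)), 1L)
  expect_false(cha2ds2_vasc_flag(row("male", 70)))        # >1 is strict
  expect_equal(cha2ds2_vasc_score(row("female", 76, stroke = TRUE)), 5L)
  expect_true(cha2ds2_vasc_flag(row("female", 76, stroke = TRUE)))
  expect_equal(cha2ds2_vasc_score(row("female", 40)), 1L)
  expect_false(cha2ds2_vasc_flag(row("female", 40)))
  expect_error(cha2ds2_vasc_flag(row("male", NA)), class = "afprs_validation_error")
})

test_that("the combined comorbidity flag is a logical OR of its four inputs", {
  d <- tibble::tibble(pah = c(FALSE, FALSE), dyslipidemia = c(FALSE, TRUE),
                      chronic_resp = FALSE, chd = FALSE)
  expect_equal(combine_comorbidities(d), c(FALSE, TRUE))
  d$chd[1] <- NA
  expect_error(combine_comorbidities(d), class = "afprs_validation_error")
})
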