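# The polygenic risk score: a population-tailored unweighted count of risk
# alleles.  A variant whose listed risk allele is *protective* in this
# population (recurrence model p < 0.1 with OR < 1) is flipped, so the
# opposite allele is counted instead; the score is then dichotomized at a
# strict threshold.

#' Decide which variants to flip
#'
#' A variant is flipped iff its per-SNV association result has
#' `p_value < alpha` AND `or < 1` — a protective trend strong enough (at the
#' lenient `alpha = 0.1`) to re-orient the counted allele toward the local
#' population.  One result per panel variant is required; the decision does
#' not depend on result order.
#'
#' @param results An `afprs_assoc` tibble (or any tibble with `term`,
#'   `p_value`, `or`) whose `term`s cover every panel variant.
#' @param panel The variant panel tibble.
#' @param alpha Flip significance level (default 0.1).
#' @return An object of class `afprs_flips`: list with `flipped` (character
#'   vector of snv_ids) and `evidence` (the triggering result rows).
#' @export
decide_flips <- function(results, panel, alpha = 0.1) {
  validate_panel(panel)
  missing <- setdiff(panel$snv_id, results$term)
  if (length(missing) > 0) {
    abort(sprintf("no association result for panel variant(s): %s",
                  paste(missing, collapse = ", ")),
          class = "afprs_validation_error")
  }
  res <- results |>
    filter(.data$term %in% panel$snv_id) |>
    dplyr::distinct(.data$term, .keep_all = TRUE) |>
    arrange(match(.data$term, panel$snv_id))
  hit <- !is.na(res$p_value) & !is.na(res$or) & res$p_value < alpha & res$or < 1
  structure(list(flipped = res$term[hit],
                 evidence = res[hit, intersect(c("term", "or", "ci_low",
                                                 "ci_high", "p_value"),
                                               names(res))],
                 alpha = alpha),
            class = "afprs_flips")
}

#' @export
print.afprs_flips <- function(x, ...) {
  if (length(x$flipped) == 0) {
    cat(sprintf("<afprs_flips> no variants flipped (alpha = %g)\n", x$alpha))
  } else {
    cat(sprintf("<afprs_flips> flipped (alpha = %g): %s\n", x$alpha,
                paste(x$flipped, collapse = ", ")))
  }
  invisible(x)
}

#' Effective dosage after an optional flip
#'
#' Unflipped variants contribute the stored risk-allele dosage; flipped
#' variants contribute the count of the opposite allele, `2 - dosage`.
#' Flipping twice restores the original dosage and a heterozygote is a
#' fixed point.
#'
#' @param dosage Integer dosages in 0/1/2 (NA allowed, propagated).
#' @param flipped Logical scalar or vector.
#' @return Effective dosages.
#' @export
effective_dosage <- function(dosage, flipped) {
  if (any(!is.na(dosage) & !dosage %in% c(0L, 1L, 2L))) {
    abort("dosage must be 0, 1, 2 or missing", class = "afprs_validation_error")
  }
  flip <- rep_len(as.logical(flipped), length(dosage))
  as.integer(ifelse(flip, 2L - dosage, dosage))
}

#' Compute the unweighted polygenic risk score
#'
#' Sums effective dosages over the panel (theoretical range 0 to 2x the
#' number of variants; 16 for the default 8-SNV panel).  Missing genotype
#' handling: `"strict"` (default) makes the whole score missing,
#' `"zero_impute"` contributes 0, `"mean_impute"` contributes
#' `round(2 * f)` where `f` is the population frequency of the *effective*
#' (possibly flipped) allele.  A flipped variant whose flipped-to allele has
#' sample frequency below 0.5 triggers a warning: the flip rule targets the
#' population major allele, and such a flip signals an atypical cohort.
#'
#' @param genotypes Dosage tibble aligned with the panel.
#' @param panel The variant panel tibble.
#' @param flips An `afprs_flips` object (or NULL for no flips).
#' @param missing_policy One of `"strict"`, `"zero_impute"`, `"mean_impute"`.
#' @return A tibble: `subject_id`, `score` (integer, NA under strict policy
#'   with missing genotypes), `n_missing`.
#' @export
compute_prs <- function(genotypes, panel, flips = NULL,
                        missing_policy = c("strict", "zero_impute", "mean_impute")) {
  missing_policy <- rlang::arg_match(missing_policy)
  validate_genotypes(genotypes, panel)
  flipped_ids <- if (is.null(flips)) character(0) else flips$flipped
  bad <- setdiff(flipped_ids, panel$snv_id)
  if (length(bad) > 0) {
    abort(sprintf("flipped variant(s) not in panel: %s", paste(bad, collapse = ", ")),
          class = "afprs_validation_error")
  }
  n <- nrow(genotypes)
  contrib <- matrix(0L, nrow = n, ncol = nrow(panel),
                    dimnames = list(NULL, panel$snv_id))
  miss <- matrix(FALSE, nrow = n, ncol = nrow(panel))
  for (k in seq_len(nrow(panel))) {
    id <- panel$snv_id[k]
    is_flip <- id %in% flipped_ids
    eff <- effective_dosage(genotypes[[id]], is_flip)
    if (is_flip) {
      eff_freq <- mean(eff[!is.na(eff)]) / 2
      if (is.finite(eff_freq) && eff_freq < 0.5) {
        warn(sprintf("flipped-to allele of %s has sample frequency %.2f < 0.5; flip may not target the major allele",
                     id, eff_freq))
      }
    }
    miss[, k] <- is.na(eff)
    if (missing_policy == "mean_impute") {
      f <- if (is_flip) 1 - panel$risk_allele_freq[k] else panel$risk_allele_freq[k]
      eff[is.na(eff)] <- as.integer(round(2 * f))
    } else {
      eff[is.na(eff)] <- 0L
    }
    contrib[, k] <- eff
  }
  score <- as.integer(rowSums(contrib))
  n_missing <- as.integer(rowSums(miss))
  if (missing_policy == "strict") score[n_missing > 0] <- NA_integer_
  tibble(subject_id = genotypes$subject_id, score = score, n_missing = n_missing)
}

#' Dichotomize polygenic scores at a strict threshold
#'
#' Adds `above_threshold = score > threshold` (strict: a score equal to the
#' threshold is below).  Missing scores give missing flags.
#'
#' @param prs A tibble from [compute_prs()].
#' @param threshold Integer threshold (default 7).
#' @return The input tibble with an `above_threshold` logical column.
#' @export
dichotomize <- function(prs, threshold = 7L) {
  assert_columns(prs, "score", "PRS table")
  prs |> mutate(above_threshold = .data$score > threshold)
}
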