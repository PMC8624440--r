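# broom-style accessors for the package's result objects.

#' Tidy association results
#'
#' `afprs_assoc` tibbles are already tidy (one row per model term); `tidy()`
#' returns them unchanged apart from stripping the subclass.
#'
#' @param x An `afprs_assoc` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.afprs_assoc <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' Tidy the flip decision
#'
#' @param x An `afprs_flips` object.
#' @param ... Unused.
#' @return A tibble with one row per panel variant considered for flipping
#'   (the evidence rows of the flipped variants).
#' @export
tidy.afprs_flips <- function(x, ...) {
  ev <- as_tibble(x$evidence)
  if (nrow(ev) == 0) return(tibble(term = character(0), or = numeric(0),
                                   p_value = numeric(0)))
  ev
}

#' Tidy a study report
#'
#' Stacks every fitted model term of the report into one tibble with a
#' `.stage` column (`snv_occurrence`, `snv_recurrence`, `occurrence_prs`,
#' `recurrence_prs`, `echo`).
#'
#' @param x An `afprs_study` object.
#' @param ... Unused.
#' @return A tibble of model terms.
#' @export
tidy.afprs_study <- function(x, ...) {
  pieces <- c(list(snv_occurrence = x$snv_occurrence,
                   snv_recurrence = x$snv_recurrence),
              x$prs_models)
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  bind_rows(purrr::imap(pieces, function(tbl, nm) {
    as_tibble(as.data.frame(tbl)) |> mutate(.stage = nm, .before = 1)
  }))
}

#' One-row summary of a study report
#'
#' @param x An `afprs_study` object.
#' @param ... Unused.
#' @return A one-row tibble: subject counts, recurrence fraction, number of
#'   flipped variants, maximum observed score, number of subjects above the
#'   threshold.
#' @export
glance.afprs_study <- function(x, ...) {
  prs <- x$prs
  tibble(
    n_cases = sum(prs$af_case),
    n_controls = sum(!prs$af_case),
    n_followed = sum(!is.na(prs$recurred)),
    n_recurred = sum(prs$recurred, na.rm = TRUE),
    recurrence_fraction = mean(prs$recurred[!is.na(prs$recurred)]),
    n_flipped = length(x$flips$flipped),
    max_score = suppressWarnings(max(prs$score, na.rm = TRUE)),
    n_above_threshold = sum(prs$prs_above, na.rm = TRUE))
}

#' One-row summary of a synthetic cohort
#'
#' @param x An `afprs_cohort` object.
#' @param ... Unused.
#' @return A one-row tibble of structural counts.
#' @export
glance.afprs_cohort <- function(x, ...) {
  ph <- x$phenotypes
  tibble(
    n_cases = sum(ph$af_case), n_controls = sum(!ph$af_case),
    n_followed = sum(!is.na(ph$recurred)),
    n_recurred = sum(ph$recurred, na.rm = TRUE),
    n_echo = sum(!is.na(ph$ef_percent) & !is.na(ph$lavi)),
    seed = x$config$seed)
}
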