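# ggplot2 displays for the result types.  Core analysis functions emit data
# only; these are convenience renderings.

#' Forest plot of odds ratios
#'
#' Points are odds ratios with 95% CI bars on a log scale; variants that the
#' flip rule re-orients (p < 0.1, OR < 1) are marked.
#'
#' @param object An `afprs_forest` tibble from [render_forest_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.afprs_forest <- function(object, ...) {
  d <- object |>
    mutate(term = factor(.data$term, levels = rev(.data$term)),
           marker = ifelse(.data$flip_marker, "flipped (p<0.1, OR<1)", "kept"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$marker), size = 2.5,
                        na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`flipped (p<0.1, OR<1)` = 8,
                                           kept = 16), name = NULL) +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.afprs_forest
#' @export
plot_forest <- function(object, ...) autoplot.afprs_forest(object, ...)

#' Polygenic score distribution by recurrence outcome
#'
#' Bar chart of the per-subject scores of followed cases, split by whether
#' AF recurred.
#'
#' @param study An `afprs_study` report.
#' @return A ggplot object.
#' @export
plot_prs_distribution <- function(study) {
  d <- study$prs |>
    filter(!is.na(.data$recurred), !is.na(.data$score)) |>
    mutate(outcome = ifelse(.data$recurred, "AF recurred", "no recurrence"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$outcome)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = scales_int_breaks(d$score)) +
    ggplot2::labs(x = "polygenic risk score (risk alleles)", y = "patients",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

scales_int_breaks <- function(x) {
  if (length(x) == 0) return(0)
  seq(min(x), max(x))
}
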