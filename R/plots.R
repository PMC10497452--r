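# ggplot2 views of the result tables: ICC heatmaps, Bland-Altman
# scatter, reliability and participant-ratio heatmaps.

#' Heatmap of ICC values
#'
#' Structures by comparison unit (scanner or scanner pair), faceted by
#' software — the standard at-a-glance view of a reliability study.
#'
#' @param icc_tbl Output of [icc_table()].
#' @return A ggplot object.
#' @export
plot_icc_heatmap <- function(icc_tbl) {
  ggplot2::ggplot(icc_tbl,
                  ggplot2::aes(x = .data$unit, y = .data$structure,
                               fill = .data$icc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$icc)),
                       size = 3) +
    ggplot2::facet_wrap(~software) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#fddbc7",
                                  high = "#2166ac", midpoint = 0.75,
                                  limits = c(NA, 1), name = "ICC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a reliability metric (SEM or SDC)
#'
#' @param rel_tbl Output of [summarize_reliability()].
#' @param metric One of `"sem_within_pct"`, `"sem_between_pct"`,
#'   `"sdc_within_pct"`, `"sdc_between_pct"`.
#' @return A ggplot object.
#' @export
plot_reliability_heatmap <- function(rel_tbl,
                                     metric = "sdc_between_pct") {
  stopifnot(metric %in% c("sem_within_pct", "sem_between_pct",
                          "sdc_within_pct", "sdc_between_pct"))
  ggplot2::ggplot(rel_tbl,
                  ggplot2::aes(x = .data$software, y = .data$structure,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data[[metric]])), size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08306b",
                                 name = "% of mean") +
    ggplot2::labs(x = NULL, y = NULL, title = metric) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Difference vs pair mean with the bias line, the 1.96-SD limits of
#' agreement, and the proportional-bias regression line.
#'
#' @param object A `"bland_altman"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "#b2182b") +
    ggplot2::labs(x = "Mean of pair", y = "Difference",
                  title = sprintf("Bland-Altman: %s",
                                  object$scanner_pair)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the between/within participant ratio
#'
#' Per (software, structure), the ratio of participants needed under
#' between-scanner vs within-scanner measurement, annotated with the
#' between-scanner n.
#'
#' @param power_tbl Output of [power_table()].
#' @return A ggplot object.
#' @export
plot_power_ratio <- function(power_tbl) {
  ggplot2::ggplot(power_tbl,
                  ggplot2::aes(x = .data$software, y = .data$structure,
                               fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f (%d)", .data$ratio,
                                   .data$n_between)), size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#67000d",
                                 name = "between / within") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidiers for volagree result objects
#'
#' [generics::tidy()] returns the per-estimate table of a result object;
#' [generics::glance()] returns one-row fit diagnostics.
#'
#' @param x A volagree result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_volagree
NULL
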