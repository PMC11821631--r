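#' Cohort-mean percent-change trajectory of a parameter
#'
#' Plots the cohort mean (+/- SD ribbon) of the percent change from
#' baseline across the measurement schedule for one parameter.
#'
#' @param params Wide parameter tibble (`subject`, `timepoint`, parameter
#'   columns).
#' @param parameter Parameter column to plot.
#' @param baseline Baseline timepoint label.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(params, parameter = "Pt", baseline = "Pre2") {
  pc <- percent_change_table(params, baseline = baseline,
                             parameters = parameter) %>%
    dplyr::group_by(.data$timepoint) %>%
    dplyr::summarise(m = mean(.data$pct_change, na.rm = TRUE),
                     s = sd(.data$pct_change, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$timepoint, y = .data$m,
                                   group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = paste0(parameter, " change from ",
                                       baseline, " (%)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn reliability_table Plot ICC point estimates with their 95%
#'   confidence intervals per parameter.
#' @param object A `tmg_reliability` tibble.
#' @param ... Unused.
#' @export
autoplot.tmg_reliability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$parameter,
                                                  .data$icc),
                               y = .data$icc)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$icc_lo,
                                          ymax = .data$icc_hi)) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.75, 0.9),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ICC(A,1) with 95% CI") +
    ggplot2::theme_minimal()
}

#' @describeIn diagnostic_table Plot sensitivity and specificity with exact
#'   intervals per parameter, faceted by timepoint.
#' @param object A `tmg_diagnostics` tibble.
#' @param ... Unused.
#' @export
autoplot.tmg_diagnostics <- function(object, ...) {
  d <- object %>%
    tidyr::pivot_longer(
      cols = c("sn", "sp"), names_to = "metric", values_to = "estimate") %>%
    dplyr::mutate(
      lo = ifelse(.data$metric == "sn", .data$sn_lo, .data$sp_lo),
      hi = ifelse(.data$metric == "sn", .data$sn_hi, .data$sp_hi),
      metric = dplyr::recode(.data$metric, sn = "sensitivity",
                             sp = "specificity"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$estimate,
                                  colour = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::facet_wrap(~timepoint) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion (95% exact CI)", colour = NULL) +
    ggplot2::theme_minimal()
}
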