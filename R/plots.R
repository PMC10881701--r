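#' Boxplot of paired T/N ratios by arm
#'
#' The primary-endpoint view: control-lobe versus intra-arterially treated
#' lobe T/N at one cycle, with within-patient pairs joined.
#'
#' @param data Paired T/N tibble (`patient_id`, `cycle`, `basis`, `tn_ia`,
#'   `tn_control`).
#' @param cycle,basis Which slice to plot.
#' @return A ggplot object.
#' @export
plot_tn_pairs <- function(data, cycle = 1L, basis = "mean") {
  long <- tn_long(select_pairs(data, cycle, basis))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$tn)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.35) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_discrete(labels = c(control = "Control lobe",
                                         ia = "Intra-arterial lobe")) +
    ggplot2::labs(x = NULL, y = "T/N uptake ratio",
                  title = sprintf("Paired T/N ratios (cycle %s, %s basis)",
                                  paste(cycle, collapse = ","), basis)) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of per-lobe diameter response
#'
#' Relative change of the target-lesion diameter sum from baseline, one bar
#' per patient-lobe, coloured by arm; each patient appears twice (both lobes).
#'
#' @param assessments Output of [assess_response()].
#' @param randomization Tibble with `patient_id`, `ia_lobe`.
#' @param timepoint `"3mo"` or `"6mo"`.
#' @return A ggplot object.
#' @export
plot_response_waterfall <- function(assessments, randomization,
                                    timepoint = "6mo") {
  x <- assessments |>
    dplyr::filter(.data$timepoint == !!timepoint) |>
    dplyr::inner_join(randomization[, c("patient_id", "ia_lobe")],
                      by = "patient_id") |>
    dplyr::mutate(arm = ifelse(.data$lobe == .data$ia_lobe,
                               "intra-arterial", "control")) |>
    dplyr::arrange(dplyr::desc(.data$percent_change_baseline)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(x, ggplot2::aes(x = .data$rank,
                                  y = .data$percent_change_baseline,
                                  fill = .data$arm)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-30, 20), linetype = "dashed") +
    ggplot2::labs(x = "Patient-lobe (ranked)",
                  y = "Diameter sum change from baseline (%)",
                  fill = NULL,
                  title = sprintf("Per-lobe response at %s", timepoint)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tn_pairs
#' @param object An `analysis_report`.
#' @param ... Passed to [plot_tn_pairs()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.analysis_report <- function(object, ...) {
  if (is.null(object$tn)) {
    abort("The report carries no T/N table; run the 'quantify' stage first.")
  }
  plot_tn_pairs(object$tn, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
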