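## ggplot2 visualisations for the main result types.

#' Plot a dose-response fit
#'
#' Points are the fitted measurements; the line is the fitted two-parameter
#' logistic, with the IC50 marked.
#'
#' @param object An `ic50_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ic50_fit <- function(object, ...) {
  grid <- tibble(
    conc = 10^seq(log10(min(object$data$conc)), log10(max(object$data$conc)),
                  length.out = 200)
  )
  grid$inhibition <- predict(object, grid$conc)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$inhibition)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (M)", y = "inhibition (%)",
      title = sprintf("IC50 = %.3g M (pIC50 = %.2f), Hill = %.2f",
                      object$ic50, object$pic50, object$hill)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-stage counts of a screening cascade
#'
#' @param object A `cascade_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cascade_report <- function(object, ...) {
  long <- object$stages |>
    tidyr::pivot_longer(c("n_pass", "n_fail", "n_new_fragments"),
                        names_to = "outcome", values_to = "count") |>
    mutate(
      stage = factor(.data$stage, levels = object$stages$stage),
      outcome = factor(.data$outcome, levels = c("n_pass", "n_new_fragments", "n_fail"),
                       labels = c("pass", "new fragments", "fail"))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$count,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "peptides", fill = NULL,
                  title = "Screening cascade stage counts") +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve with its fitted line
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_curve <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "standard concentration", y = "response",
                  title = sprintf("Calibration: R^2 = %.4f (n = %d)",
                                  object$r_squared, object$n_points)) +
    ggplot2::theme_minimal()
}

#' Plot hydrolysis statistics across treatments
#'
#' @param report Tibble from [hydrolysis_report()].
#' @return A ggplot of DH (and A_E/W when present) per treatment.
#' @export
plot_hydrolysis <- function(report) {
  cols <- intersect(c("dh", "ae", "w"), names(report))
  long <- report |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "statistic",
                        values_to = "value") |>
    mutate(treatment = factor(.data$treatment, levels = report$treatment))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$treatment, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Simulated hydrolysis statistics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a per-residue RMSF profile
#'
#' @param rmsf_tbl Tibble from [rmsf()].
#' @return A ggplot.
#' @export
plot_rmsf <- function(rmsf_tbl) {
  ggplot2::ggplot(rmsf_tbl, ggplot2::aes(x = .data$resid, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
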