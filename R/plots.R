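#' Plot paired vs unpaired power curves
#'
#' @param object a [power_paired_vs_unpaired()] tibble (class
#'   `gp_power_curve`).
#' @param ... unused.
#' @return A ggplot: power against fold correlation for both designs.
#' @export
autoplot.gp_power_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("power_paired", "power_unpaired"),
                              names_to = "design", values_to = "power",
                              names_prefix = "power_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rho, y = .data$power,
                                     colour = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fold-score correlation between models",
                  y = "power", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison as difference intervals against the reference
#'
#' @param object a [compare_models()] object.
#' @param ... unused.
#' @return A ggplot: mean difference and interval per model, with the
#'   equivalence margin shaded.
#' @export
autoplot.gp_comparison <- function(object, ...) {
  rep_tab <- report_comparison(object)
  rep_tab$model <- factor(rep_tab$model, levels = rep_tab$model)
  delta <- object$margin$delta
  ggplot2::ggplot(rep_tab, ggplot2::aes(x = .data$mean, y = .data$model)) +
    ggplot2::annotate("rect", xmin = -delta, xmax = delta,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("difference vs %s (%s scale)",
                              object$reference %||% object$models[1],
                              object$scale),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.gp_power_curve
#' @param true_d,sd_fold,rho,k,alpha passed to
#'   [power_paired_vs_unpaired()].
#' @export
plot_power_curve <- function(true_d, sd_fold, rho = seq(0, 0.99, by = 0.01),
                             k = 10, alpha = 0.05) {
  autoplot(power_paired_vs_unpaired(true_d, sd_fold, rho, k, alpha))
}
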