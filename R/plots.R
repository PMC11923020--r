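#' Plot the attenuation of Cohen's d by unreliability
#'
#' Observed (attenuated) d as a function of reliability for a fixed true
#' effect, with the percent-bias curve `100 (1 - sqrt(reliability))` on a
#' secondary panel-free scale via a second line.
#'
#' @param true_d True standardized mean difference.
#' @param from,to Reliability range.
#' @return A ggplot object.
#' @export
plot_attenuation <- function(true_d = 1, from = 0.3, to = 1) {
  rel <- seq(from, to, length.out = 200)
  df <- tibble(reliability = rel, observed_d = attenuated_d(true_d, rel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reliability, y = .data$observed_d)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = true_d, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.8, linetype = "dotted") +
    ggplot2::labs(
      x = "Reliability",
      y = "Observed d",
      title = sprintf("Attenuation of a true d of %.2f", true_d),
      subtitle = "Dotted line: reliability 0.80, below which bias exceeds 10%"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of latent versus observed standardized mean differences
#'
#' One point per scale; the diagonal marks equality, dashed lines a band of
#' +/- 0.1 SD around it.
#'
#' @param object A `latentdiff_study`.
#' @param band Half-width of the agreement band (SD units).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot latentdiff_study
#' @export
autoplot.latentdiff_study <- function(object, band = 0.1, ...) {
  df <- object$comparisons
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_y, y = .data$d_tau)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-band, band),
                         linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$omega), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Observed d (sum score)", y = "Latent d",
                  colour = expression(omega)) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of signed discrepancies
#'
#' Signed `|d_tau| - |d_y|` per scale with its 95% confidence interval and,
#' when available, the pooled random-effects estimate as a vertical line.
#'
#' @param study A `latentdiff_study`.
#' @return A ggplot object.
#' @export
plot_discrepancies <- function(study) {
  df <- arrange(study$comparisons, .data$signed_delta_d)
  df$scale <- factor(df$scale, levels = df$scale)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_delta_d, y = .data$scale)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("signed " * Delta * d), y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(study$meta)) {
    p <- p + ggplot2::geom_vline(xintercept = study$meta$signed$estimate,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
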