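#' Classical test theory attenuation, in closed form
#'
#' Under classical test theory an observed score decomposes as
#' \eqn{X = \tau + \varepsilon} with uncorrelated error, so
#' \eqn{\sigma^2_X = \sigma^2_\tau + \sigma^2_\varepsilon}. Reliability
#' \eqn{\rho = \sigma^2_\tau / \sigma^2_X} therefore inflates the observed
#' variance by \eqn{1/\rho} and shrinks a standardized mean difference
#' (Cohen's d) by \eqn{\sqrt{\rho}}. These helpers return the exact
#' consequences of that decomposition.
#'
#' @param reliability Proportion of observed-score variance attributable to
#'   the true score, in (0, 1].
#' @param var_tau True-score variance (> 0). Default 1.
#' @return `error_variance()` and `observed_variance()` return variances in
#'   squared score units; `attenuated_d()` returns a standardized mean
#'   difference; `relative_bias_pct()` returns the percent shrinkage
#'   `100 * (1 - sqrt(reliability))`.
#' @examples
#' observed_variance(0.8)          # 1.25
#' attenuated_d(1, 0.5)            # 0.707...
#' relative_bias_pct(0.8)          # 10.56 percent: the >10% rule of thumb
#' @name ctt_attenuation
NULL

check_reliability <- function(reliability) {
  if (!is.numeric(reliability) || anyNA(reliability) ||
      any(reliability <= 0) || any(reliability > 1)) {
    abort("`reliability` must lie in (0, 1].")
  }
  invisible(reliability)
}

check_var_tau <- function(var_tau) {
  if (!is.numeric(var_tau) || anyNA(var_tau) || any(var_tau <= 0)) {
    abort("`var_tau` must be > 0.")
  }
  invisible(var_tau)
}

#' @rdname ctt_attenuation
#' @export
error_variance <- function(reliability, var_tau = 1) {
  check_reliability(reliability)
  check_var_tau(var_tau)
  var_tau * (1 - reliability) / reliability
}

#' @rdname ctt_attenuation
#' @export
observed_variance <- function(reliability, var_tau = 1) {
  check_reliability(reliability)
  check_var_tau(var_tau)
  var_tau / reliability
}

#' @rdname ctt_attenuation
#' @param true_d Standardized mean difference on the true-score metric.
#' @export
attenuated_d <- function(true_d, reliability) {
  check_reliability(reliability)
  true_d * sqrt(reliability)
}

#' @rdname ctt_attenuation
#' @export
relative_bias_pct <- function(reliability) {
  check_reliability(reliability)
  100 * (1 - sqrt(reliability))
}

#' Attenuation table for a set of reliabilities
#'
#' Tabulates, for a fixed true mean difference and true-score variance, the
#' error variance, observed variance and observed (attenuated) Cohen's d at
#' each reliability. With the defaults (`delta_mu = 1`, `var_tau = 1`) the
#' true d is 1 and the observed d is `sqrt(reliability)`.
#'
#' @param reliabilities Numeric vector of reliabilities in (0, 1].
#' @param delta_mu True mean difference between the groups.
#' @param var_tau True-score variance.
#' @param digits Optional number of decimals for presentation; the default
#'   `NULL` keeps full precision.
#' @return A tibble with columns `reliability`, `error_variance`,
#'   `observed_variance`, `observed_d`.
#' @examples
#' attenuation_table(digits = 2)
#' @export
attenuation_table <- function(reliabilities = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                              delta_mu = 1, var_tau = 1, digits = NULL) {
  check_reliability(reliabilities)
  out <- tibble(
    reliability       = reliabilities,
    error_variance    = error_variance(reliabilities, var_tau),
    observed_variance = observed_variance(reliabilities, var_tau),
    observed_d        = attenuated_d(delta_mu / sqrt(var_tau), reliabilities)
  )
  if (!is.null(digits)) {
    out <- mutate(out, dplyr::across(-"reliability", ~ round(.x, digits)))
  }
  out
}
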