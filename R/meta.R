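#' Random-effects meta-analysis of per-scale discrepancies
#'
#' Pools effect-size discrepancies across scales under a random-effects
#' model, delegating estimation to [metafor::rma()]. The between-scale
#' variance `tau2` is estimated by REML (default) or DerSimonian–Laird; the
#' pooled estimate is the inverse-variance weighted mean with weights
#' `1/(v_i + tau2)`; Cochran's Q uses fixed-effect weights `1/v_i`; and
#' `I2 = 100 * tau2 / (tau2 + v_typ)` with the usual typical within-scale
#' variance `v_typ = (k-1) * sum(w) / (sum(w)^2 - sum(w^2))`.
#'
#' @param effects Numeric vector of per-scale discrepancies (length k >= 2).
#' @param variances Their sampling variances (> 0).
#' @param method `"REML"` or `"DL"`.
#' @return One-row tibble of class `meta_result`: `k`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `Q`, `df`, `p_Q`, `I2` (percent), `tau2`,
#'   `tau`, `method`.
#' @examples
#' random_effects_meta(c(0.1, 0.3), c(0.01, 0.01), method = "DL")
#' @export
random_effects_meta <- function(effects, variances, method = c("REML", "DL")) {
  method <- match.arg(method)
  if (length(effects) < 2L) abort("At least 2 effects are required.")
  if (length(effects) != length(variances)) {
    abort("`effects` and `variances` must have equal length.")
  }
  if (any(variances <= 0)) abort("All `variances` must be > 0.")
  fit <- metafor::rma(yi = effects, vi = variances, method = method,
                      test = "z")
  out <- tibble(
    k = length(effects),
    estimate = as.numeric(fit$beta), se = fit$se,
    ci_low = fit$ci.lb, ci_high = fit$ci.ub, p = fit$pval,
    Q = fit$QE, df = length(effects) - 1L, p_Q = fit$QEp,
    I2 = fit$I2, tau2 = fit$tau2, tau = sqrt(fit$tau2),
    method = method
  )
  class(out) <- c("meta_result", class(out))
  out
}

#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) as_tibble(x)

#' Expected share of scales beyond a discrepancy cutoff
#'
#' Treats the scale-level discrepancies as Normal(`pooled`, `tau^2`) — the
#' random-effects model's distribution of true effects — and returns the
#' percent expected to exceed `cutoff`.
#'
#' @param pooled Pooled discrepancy estimate.
#' @param tau Between-scale standard deviation (> 0), same metric as the
#'   discrepancy.
#' @param cutoff Discrepancy threshold.
#' @return Percent (0-100).
#' @examples
#' exceedance_probability(0.028, 0.074, 0.200)  # about 1 percent
#' @export
exceedance_probability <- function(pooled, tau, cutoff) {
  if (tau <= 0) abort("`tau` must be > 0.")
  100 * pnorm((cutoff - pooled) / tau, lower.tail = FALSE)
}

#' Correlation between scale reliability and effect-size discrepancy
#'
#' Pearson or Spearman correlation of per-scale reliabilities (omega) with
#' per-scale discrepancies, with a Fisher-z 95% confidence interval and a
#' two-sided p-value. The Fisher-z interval for the Spearman coefficient is
#' the common large-sample approximation applied to the rank correlation.
#'
#' @param omegas Per-scale reliability estimates.
#' @param discrepancies Per-scale discrepancies (absolute or percent),
#'   same length (>= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `method`, `estimate`, `ci_low`, `ci_high`, `p`,
#'   `df` (`n - 2`), `n`.
#' @export
omega_discrepancy_cor <- function(omegas, discrepancies,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(omegas)
  if (n < 4L || length(discrepancies) != n) {
    abort("Need >= 4 paired observations of equal length.")
  }
  if (sd(omegas) == 0 || sd(discrepancies) == 0) {
    abort("Zero variance in one of the inputs.")
  }
  if (method == "pearson") {
    ct <- cor.test(omegas, discrepancies, method = "pearson")
    est <- unname(ct$estimate); ci <- ct$conf.int; p <- ct$p.value
  } else {
    ct <- suppressWarnings(
      cor.test(omegas, discrepancies, method = "spearman", exact = FALSE)
    )
    est <- unname(ct$estimate)
    zse <- 1 / sqrt(n - 3)
    ci <- tanh(atanh(est) + c(-1, 1) * qnorm(0.975) * zse)
    p <- ct$p.value
  }
  tibble(method = method, estimate = est, ci_low = ci[1], ci_high = ci[2],
         p = p, df = n - 2L, n = n)
}
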