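#' Sampling variance of Cohen's d
#'
#' `var_d = (n1 + n2)/(n1 * n2) + d^2 / (2 * (n1 + n2))` — symmetric in the
#' group sizes and increasing in `|d|`.
#'
#' @param d Standardized mean difference.
#' @param n1,n2 Group sizes (>= 2).
#' @return Sampling variance of `d`.
#' @examples
#' d_variance(0.5, 100, 100)  # 0.020625
#' @export
d_variance <- function(d, n1, n2) {
  if (any(c(n1, n2) < 2)) abort("Group sizes must be >= 2.")
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)   # avoid integer overflow
  (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
}

#' Bundle a standardized mean difference with its sampling variance
#'
#' @param d Standardized mean difference.
#' @param n1,n2 Group sizes.
#' @return One-row tibble of class `effect_estimate` with columns `d`,
#'   `n1`, `n2`, `var_d`.
#' @export
effect_estimate <- function(d, n1, n2) {
  out <- tibble(d = d, n1 = n1, n2 = n2, var_d = d_variance(d, n1, n2))
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Cohen's d between two groups
#'
#' Mean of group 1 minus mean of group 2, divided by the pooled standard
#' deviation `sqrt(((n1-1) s1^2 + (n2-1) s2^2)/(n1+n2-2))`. Group 1 is the
#' first group level in sorted order. Scale-free: sum- and mean-scored
#' versions of the same scale give identical d.
#'
#' @param scores Numeric vector of observed scores.
#' @param groups Two-level grouping vector aligned with `scores`.
#' @return An [effect_estimate()] row.
#' @examples
#' cohens_d(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))$d  # -2
#' @export
cohens_d <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) abort("Exactly two groups are required.")
  s1 <- scores[groups == levels(groups)[1]]
  s2 <- scores[groups == levels(groups)[2]]
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2L || n2 < 2L) abort("Both groups need at least 2 observations.")
  sd_pool <- sqrt(((n1 - 1) * var(s1) + (n2 - 1) * var(s2)) / (n1 + n2 - 2))
  if (sd_pool <= 0) abort("Pooled standard deviation is zero.")
  effect_estimate((mean(s1) - mean(s2)) / sd_pool, n1, n2)
}

#' Compare a latent and an observed standardized mean difference
#'
#' Discrepancy statistics between the latent (`d_tau`) and observed
#' (`d_y`) effect for one scale. The signed discrepancy is the difference
#' of magnitudes, `|d_tau| - |d_y|` (positive when excising measurement
#' error enlarges the effect); `delta_d` is its absolute value. Percent
#' change uses the symmetric mean-of-magnitudes denominator
#' `(|d_tau| + |d_y|)/2`. The z statistic divides the signed discrepancy by
#' `sqrt(var_d_tau + var_d_y)` — the two estimates are treated as
#' independent, which overstates the variance of their difference (they
#' share a sample) and so is conservative. The one-tailed p-value is the
#' upper-tail probability (alternative: the latent effect exceeds the
#' observed one in magnitude, as attenuation predicts), and the 95% CI is
#' `signed_delta_d +/- 1.96 * SE`.
#'
#' @param d_tau,d_y [effect_estimate()] rows (or lists with `d`, `var_d`).
#' @return One-row tibble of class `effect_comparison` with columns
#'   `d_tau`, `d_y`, `var_d_tau`, `var_d_y`, `delta_d`, `signed_delta_d`,
#'   `pct_change`, `signed_pct_change`, `z`, `p`, `ci_low`, `ci_high`.
#'   When both effects are exactly zero the percent change is undefined and
#'   reported as `NA`.
#' @examples
#' compare_ds(effect_estimate(-0.151, 500, 500),
#'            effect_estimate(-0.095, 500, 500))$delta_d  # 0.056
#' @export
compare_ds <- function(d_tau, d_y) {
  dt <- d_tau$d; vt <- d_tau$var_d
  dy <- d_y$d; vy <- d_y$var_d
  signed <- abs(dt) - abs(dy)
  delta <- abs(signed)
  denom <- (abs(dt) + abs(dy)) / 2
  pct <- if (denom == 0) NA_real_ else 100 * delta / denom
  se <- sqrt(vt + vy)
  z <- signed / se
  out <- tibble(
    d_tau = dt, d_y = dy,
    var_d_tau = vt, var_d_y = vy,
    delta_d = delta, signed_delta_d = signed,
    pct_change = pct,
    signed_pct_change = if (is.na(pct)) NA_real_ else sign(signed) * pct,
    z = z, p = pnorm(z, lower.tail = FALSE),
    ci_low = signed - qnorm(0.975) * se,
    ci_high = signed + qnorm(0.975) * se
  )
  class(out) <- c("effect_comparison", class(out))
  out
}

apply_reverse_keys <- function(data, sdef) {
  if (!length(sdef$reverse_keyed)) return(data)
  max_cat <- sdef$n_categories %||%
    (max(as.matrix(data[sdef$items]), na.rm = TRUE) + 1L)
  for (it in sdef$reverse_keyed) data[[it]] <- (max_cat - 1L) - data[[it]]
  data
}

#' Observed versus latent group comparison for one scale
#'
#' The per-scale pipeline: reverse-key items, score the scale and compute
#' the observed Cohen's d (`d_y`); fit the invariance-constrained two-group
#' ordinal factor model and compute the latent d (`d_tau`) and McDonald's
#' omega; then form the discrepancy statistics. Both effects use the Choi &
#' Lam sampling variance [d_variance()].
#'
#' @param data Data frame of integer item columns and a two-level group
#'   column.
#' @param sdef A [scale_def()].
#' @param group_col Name of the group column.
#' @param estimator Passed to [fit_mgcfa()].
#' @param ... Further arguments to [fit_mgcfa()].
#' @return One-row tibble: `scale`, the [compare_ds()] columns, `omega`,
#'   `n1`, `n2`.
#' @export
compare_groups <- function(data, sdef, group_col = "group",
                           estimator = "DWLS", ...) {
  stopifnot(inherits(sdef, "scale_def"))
  keyed <- apply_reverse_keys(data, sdef)
  sdef_keyed <- sdef
  sdef_keyed$reverse_keyed <- character()   # keying already applied
  scored <- score_scale(keyed, sdef_keyed, group_col = group_col)
  d_y <- cohens_d(scored$score, scored$group)
  fit <- fit_mgcfa(keyed, items = sdef$items, group_col = group_col,
                   estimator = estimator, ...)
  d_tau <- effect_estimate(latent_d(fit), fit$n1, fit$n2)
  cmp <- compare_ds(d_tau, d_y)
  out <- dplyr::bind_cols(
    tibble(scale = sdef$name), cmp,
    tibble(omega = mcdonald_omega(fit), n1 = fit$n1, n2 = fit$n2)
  )
  class(out) <- c("effect_comparison", class(out))
  out
}
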