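#' Continuous classical-test-theory scenario
#'
#' Fixes the three quantities that determine attenuation in the continuous
#' case: the true mean difference between the groups, the true-score
#' variance, and the reliability. The implied error variance is
#' `var_tau * (1 - reliability) / reliability`.
#'
#' @param delta_mu True-score mean difference (group 1 minus group 2), in
#'   score units.
#' @param var_tau True-score variance (> 0).
#' @param reliability In (0, 1].
#' @return An object of class `ctt_scenario`.
#' @export
ctt_scenario <- function(delta_mu = 1, var_tau = 1, reliability = 1) {
  check_reliability(reliability)
  check_var_tau(var_tau)
  structure(
    list(delta_mu = delta_mu, var_tau = var_tau, reliability = reliability,
         var_eps = error_variance(reliability, var_tau)),
    class = "ctt_scenario"
  )
}

#' Simulate continuous two-group scores under classical test theory
#'
#' Draws true scores for two groups whose means differ by the scenario's
#' `delta_mu` (group 1 high), then adds independent Gaussian measurement
#' error with the scenario's implied error variance. Both the true and the
#' observed score are returned so the attenuation of the standardized mean
#' difference can be checked directly.
#'
#' @param scenario A [ctt_scenario()].
#' @param n_per_group Respondents per group (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `group` (factor `"1"`, `"2"`),
#'   `true_score`, `observed_score`.
#' @examples
#' sim <- simulate_ctt(ctt_scenario(reliability = 0.5), 5000, seed = 1)
#' # observed d is attenuated toward sqrt(0.5) * true d
#' @export
simulate_ctt <- function(scenario, n_per_group, seed = NULL) {
  stopifnot(inherits(scenario, "ctt_scenario"))
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    abort("`n_per_group` must be >= 2.")
  }
  n <- as.integer(n_per_group)
  if (!is.null(seed)) set.seed(seed)
  mu <- rep(c(scenario$delta_mu, 0), each = n)
  true_score <- mu + rnorm(2L * n, sd = sqrt(scenario$var_tau))
  observed <- true_score + if (scenario$var_eps > 0) {
    rnorm(2L * n, sd = sqrt(scenario$var_eps))
  } else 0
  tibble(
    group = factor(rep(c("1", "2"), each = n)),
    true_score = true_score,
    observed_score = observed
  )
}

default_thresholds <- function(n_categories) {
  qnorm(seq_len(n_categories - 1L) / n_categories)
}

#' Configuration for the two-group ordinal factor-model generator
#'
#' Describes a unidimensional congeneric scale measured by ordinal items:
#' each latent item response is `loading * trait + residual`, and the
#' observed category counts how many thresholds the latent response
#' exceeds. Group 1's trait is standard normal; group 2's trait has variance
#' `latent_var_g2` and a mean placed so that the true standardized mean
#' difference (group 2 minus group 1) equals `latent_d` — on group 1's SD
#' scale when `latent_var_g2 == 1`, otherwise on the pooled latent SD scale.
#' Loadings and thresholds are identical in both groups (the measurement
#' invariance the downstream model assumes).
#'
#' @param n_items Number of items (>= 1; fewer than 3 draws a warning since
#'   a one-factor model is not identified below 3 items).
#' @param loadings Per-item loadings, recycled to `n_items`.
#' @param thresholds Either a numeric vector of ascending cut-points shared
#'   by all items, or a list of one such vector per item. Default: cut-points
#'   at standard-normal quantiles of `n_categories` equal probability bands
#'   (Likert-like).
#' @param residual_variances Per-item unique variances (> 0); default
#'   `1 - loadings^2`, which standardizes the latent item responses in
#'   group 1.
#' @param n_per_group Length-2 integer vector `(n1, n2)`.
#' @param latent_d True standardized latent mean difference, group 2 minus
#'   group 1 (see above for the SD scale).
#' @param latent_var_g2 Group-2 latent trait variance (> 0).
#' @param n_categories Number of response categories used for the default
#'   thresholds.
#' @param seed Optional integer seed consumed by [simulate_ordinal()].
#' @return An object of class `ordinal_config`.
#' @export
ordinal_config <- function(n_items = 6, loadings = 0.7, thresholds = NULL,
                           residual_variances = NULL,
                           n_per_group = c(1000, 1000),
                           latent_d = 0, latent_var_g2 = 1,
                           n_categories = 5, seed = NULL) {
  n_items <- as.integer(n_items)
  if (n_items < 1L) abort("`n_items` must be >= 1.")
  if (n_items < 3L) {
    warn("Fewer than 3 items: a one-factor model is not identified; data can be generated but not fitted.")
  }
  loadings <- rep_len(loadings, n_items)
  if (any(abs(loadings) > 1) && is.null(residual_variances)) {
    abort("|loadings| > 1 requires explicit `residual_variances`.")
  }
  residual_variances <- residual_variances %||% (1 - loadings^2)
  residual_variances <- rep_len(residual_variances, n_items)
  if (any(residual_variances <= 0)) abort("`residual_variances` must be > 0.")
  thresholds <- thresholds %||% default_thresholds(n_categories)
  if (!is.list(thresholds)) thresholds <- rep(list(thresholds), n_items)
  if (length(thresholds) != n_items) {
    abort("`thresholds` must have one cut-point vector per item.")
  }
  ok <- vapply(thresholds, function(t) length(t) >= 1 && !is.unsorted(t, strictly = TRUE),
               logical(1))
  if (!all(ok)) abort("Each item's thresholds must be strictly increasing.")
  if (length(n_per_group) != 2L || any(n_per_group < 2)) {
    abort("`n_per_group` must be two group sizes >= 2.")
  }
  n_per_group <- as.integer(n_per_group)
  if (any(n_per_group < 20L * n_items)) {
    warn("Group size below 20 respondents per item; estimates may be unstable.")
  }
  if (latent_var_g2 <= 0) abort("`latent_var_g2` must be > 0.")
  structure(
    list(n_items = n_items, loadings = loadings, thresholds = thresholds,
         residual_variances = residual_variances, n_per_group = n_per_group,
         latent_d = latent_d, latent_var_g2 = latent_var_g2, seed = seed),
    class = "ordinal_config"
  )
}

# group-2 latent mean implied by the configured latent_d (see ordinal_config)
latent_mean_g2 <- function(config) {
  n1 <- config$n_per_group[1]; n2 <- config$n_per_group[2]
  psi2 <- config$latent_var_g2
  scale <- if (psi2 == 1) 1 else sqrt(((n1 - 1) + (n2 - 1) * psi2) / (n1 + n2 - 2))
  config$latent_d * scale
}

#' Simulate two-group ordinal item responses
#'
#' Generates item categories under the configuration's factor model; both
#' groups use identical loadings and thresholds. Refuses to return data in
#' which any item is constant within a group, since such an item cannot
#' enter threshold or polychoric estimation.
#'
#' @param config An [ordinal_config()].
#' @param seed Integer seed; defaults to the one stored in `config`.
#' @return A tibble with 0-based integer item columns `item01`, `item02`,
#'   ... and a factor column `group` (`"1"`, `"2"`).
#' @export
simulate_ordinal <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ordinal_config"))
  if (!is.null(seed)) set.seed(seed)
  n1 <- config$n_per_group[1]; n2 <- config$n_per_group[2]
  alpha2 <- latent_mean_g2(config)
  trait <- c(rnorm(n1),
             alpha2 + sqrt(config$latent_var_g2) * rnorm(n2))
  group <- factor(rep(c("1", "2"), times = c(n1, n2)))
  resp <- matrix(0L, nrow = n1 + n2, ncol = config$n_items)
  for (j in seq_len(config$n_items)) {
    ystar <- config$loadings[j] * trait +
      rnorm(n1 + n2, sd = sqrt(config$residual_variances[j]))
    resp[, j] <- findInterval(ystar, config$thresholds[[j]])
  }
  colnames(resp) <- sprintf("item%02d", seq_len(config$n_items))
  for (j in seq_len(config$n_items)) {
    for (g in levels(group)) {
      if (length(unique(resp[group == g, j])) < 2L) {
        abort(paste0("Item ", colnames(resp)[j], " is constant in group ", g,
                     "; widen thresholds or increase the sample."),
              class = "latentdiff_degenerate_item")
      }
    }
  }
  out <- as_tibble(as.data.frame(resp))
  out$group <- group
  out
}

#' Scale definition matching a generator configuration
#'
#' @param config An [ordinal_config()].
#' @param scoring `"sum"` or `"mean"`.
#' @param name Scale label.
#' @return A [scale_def()] covering the generated item columns.
#' @export
config_scale_def <- function(config, scoring = "sum", name = "simulated") {
  stopifnot(inherits(config, "ordinal_config"))
  n_cat <- length(config$thresholds[[1]]) + 1L
  scale_def(sprintf("item%02d", seq_len(config$n_items)),
            scoring = scoring, n_categories = n_cat, name = name)
}

#' Model-implied composite reliability (McDonald's omega)
#'
#' Reliability of the unit-weighted composite of the latent item responses
#' under the configuration's factor model:
#' \deqn{\omega = (\Sigma\lambda)^2 \bar\psi /
#'       ((\Sigma\lambda)^2 \bar\psi + \Sigma\theta)}
#' with \eqn{\bar\psi} the sample-size-weighted pooled latent variance.
#' Serves as the ground truth for omega-recovery tests.
#'
#' @param config An [ordinal_config()].
#' @return Reliability in \[0, 1\].
#' @examples
#' implied_omega(ordinal_config(n_items = 6, loadings = 0.7))  # 0.852
#' @export
implied_omega <- function(config) {
  stopifnot(inherits(config, "ordinal_config"))
  n1 <- config$n_per_group[1]; n2 <- config$n_per_group[2]
  psi_bar <- (n1 + n2 * config$latent_var_g2) / (n1 + n2)
  sl2 <- sum(config$loadings)^2 * psi_bar
  sl2 / (sl2 + sum(config$residual_variances))
}
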