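# loading giving a target composite reliability for p equally loaded items
# with standardized latent responses: omega = (p*l)^2 / ((p*l)^2 + p(1-l^2))
loading_for_omega <- function(omega, p) sqrt(omega / (p - (p - 1) * omega))

# population mgcfa_stats object under the delta parameterization
population_stats <- function(lambda, tau, alpha2, psi2, n1 = 1000, n2 = 1000) {
  p <- length(lambda)
  items <- sprintf("item%02d", seq_len(p))
  sd2 <- sqrt(lambda^2 * psi2 + 1 - lambda^2)
  named <- function(v) setNames(v, as.character(seq_along(v)))
  R1 <- tcrossprod(lambda); diag(R1) <- 1; dimnames(R1) <- list(items, items)
  R2 <- tcrossprod(lambda) * psi2 / tcrossprod(sd2); diag(R2) <- 1
  dimnames(R2) <- list(items, items)
  g1 <- list(thresholds = setNames(rep(list(named(tau)), p), items),
             rho = R1, n = n1)
  g2 <- list(thresholds = setNames(lapply(seq_len(p), function(i) {
    named((tau - lambda[i] * alpha2) / sd2[i])
  }), items), rho = R2, n = n2)
  structure(
    list(items = items, group_levels = c("1", "2"),
         global_levels = setNames(rep(list(0:length(tau)), p), items),
         per_group = setNames(list(g1, g2), c("1", "2"))),
    class = "mgcfa_stats"
  )
}

# bivariate-normal contingency table simulated at a given latent correlation
simulate_pair_table <- function(n, rho, thresholds, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  table(findInterval(x, thresholds), findInterval(y, thresholds))
}
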