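test_that("fitting exact population statistics returns the generating parameters", {
  lam <- c(0.75, 0.7, 0.65, 0.6, 0.55)
  tau <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  st <- population_stats(lam, tau, alpha2 = 0.5, psi2 = 1.3)
  fit <- fit_mgcfa_stats(st, estimator = "ULS")
  expect_true(fit$converged)
  expect_equal(unname(fit$lambda), lam, tolerance = 1e-4)
  expect_equal(fit$alpha2, 0.5, tolerance = 1e-4)
  expect_equal(fit$psi2, 1.3, tolerance = 1e-4)
  expect_lt(fit$discrepancy, 1e-8)
  expect_equal(unname(fit$tau[[1]]), tau, tolerance = 1e-4)
})

test_that("latent mean difference is recovered from simulated data", {
  # recovery is a distributional property: average over a few replicates
  # (per-fit Monte-Carlo SD at this n is about 0.036)
  fits <- lapply(1:5, function(r) {
    cfg <- ordinal_config(n_items = 6, loadings = 0.7,
                          n_per_group = c(2000, 2000),
                          latent_d = 0.5, seed = 100 + r)
    fit_mgcfa(simulate_ordinal(cfg), estimator = "ULS")
  })
  a2 <- vapply(fits, `[[`, numeric(1), "alpha2")
  expect_equal(mean(a2), 0.5, tolerance = 0.07)
  expect_lt(max(abs(a2 - 0.5)), 0.15)
  expect_equal(mean(vapply(fits, function(f) abs(latent_d(f)), numeric(1))),
               0.5, tolerance = 0.07)
  # DWLS point estimates agree with ULS on the same data
  cfg <- ordinal_config(n_items = 6, loadings = 0.7,
                        n_per_group = c(2000, 2000), latent_d = 0.5,
                        seed = 101)
  d <- simulate_ordinal(cfg)
  expect_equal(fit_mgcfa(d, estimator = "DWLS")$alpha2,
               fit_mgcfa(d, estimator = "ULS")$alpha2, tolerance = 0.03)
})

test_that("identical groups yield a null latent mean difference", {
  cfg <- ordinal_config(n_items = 5, loadings = 0.7,
                        n_per_group = c(5000, 5000),
                        latent_d = 0, seed = 102)
  fit <- fit_mgcfa(simulate_ordinal(cfg), estimator = "ULS")
  expect_lt(abs(fit$alpha2), 0.05)
})

test_that("a group-2 latent variance of 1.5 is recovered", {
  cfg <- ordinal_config(n_items = 6, loadings = 0.7,
                        n_per_group = c(5000, 5000),
                        latent_d = 0.3, latent_var_g2 = 1.5, seed = 103)
  fit <- fit_mgcfa(simulate_ordinal(cfg), estimator = "ULS")
  expect_equal(fit$psi2, 1.5, tolerance = 0.15)
})

test_that("latent_d applies the pooled-SD sign convention", {
  st <- population_stats(rep(0.7, 4), qnorm(c(0.25, 0.5, 0.75)),
                         alpha2 = 0, psi2 = 1)
  fit0 <- fit_mgcfa_stats(st, estimator = "ULS")
  expect_equal(latent_d(fit0), 0, tolerance = 1e-4)

  st_neg <- population_stats(rep(0.7, 4), qnorm(c(0.25, 0.5, 0.75)),
                             alpha2 = -0.5, psi2 = 1)
  fit_neg <- fit_mgcfa_stats(st_neg, estimator = "ULS")
  expect_equal(latent_d(fit_neg), 0.5, tolerance = 1e-3)

  st2 <- population_stats(rep(0.7, 4), qnorm(c(0.25, 0.5, 0.75)),
                          alpha2 = 0.5, psi2 = 2)
  fit2 <- fit_mgcfa_stats(st2, estimator = "ULS")
  expect_equal(latent_d(fit2), -0.5 / sqrt(1.5), tolerance = 1e-3)
})

test_that("McDonald's omega matches the closed form and is recovered from data", {
  st <- population_stats(rep(0.7, 6), qnorm(c(0.2, 0.4, 0.6, 0.8)),
                         alpha2 = 0, psi2 = 1)
  fit <- fit_mgcfa_stats(st, estimator = "ULS")
  expect_equal(mcdonald_omega(fit), 4.2^2 / (4.2^2 + 3.06), tolerance = 1e-3)

  cfg <- ordinal_config(n_items = 6, loadings = 0.7,
                        n_per_group = c(5000, 5000), latent_d = 0.2,
                        seed = 104)
  fit2 <- fit_mgcfa(simulate_ordinal(cfg), estimator = "ULS")
  expect_equal(mcdonald_omega(fit2), implied_omega(cfg), tolerance = 0.03)
})

test_that("swapping group labels flips latent_d and preserves omega", {
  cfg <- ordinal_config(n_items = 5, loadings = 0.7,
                        n_per_group = c(2000, 2000), latent_d = 0.4,
                        seed = 105)
  d <- simulate_ordinal(cfg)
  d2 <- d
  d2$group <- factor(ifelse(d$group == "1", "2", "1"))
  fit <- fit_mgcfa(d, estimator = "ULS")
  fit2 <- fit_mgcfa(d2, estimator = "ULS")
  expect_equal(latent_d(fit2), -latent_d(fit), tolerance = 0.02)
  expect_equal(mcdonald_omega(fit2), mcdonald_omega(fit), tolerance = 0.02)
})

test_that("a duplicated item drives the solution to a Heywood condition", {
  cfg <- ordinal_config(n_items = 3, loadings = c(0.8, 0.8, 0.5),
                        n_per_group = c(300, 300), seed = 3)
  d <- suppressWarnings(simulate_ordinal(cfg))
  d$item02 <- d$item01
  err <- tryCatch(fit_mgcfa(d, estimator = "ULS"), error = function(e) e)
  expect_s3_class(err, "latentdiff_heywood")
  expect_true(all(c("item01", "item02") %in% err$items))
})

test_that("the constrained fitter matches a brute-force grid search", {
  # 3 binary items, shared loading and threshold, psi2 fixed: 3 free
  # parameters, small enough to enumerate
  cfg <- ordinal_config(n_items = 3, loadings = 0.6, thresholds = 0,
                        n_per_group = c(300, 300), latent_d = 0.4, seed = 55)
  d <- suppressWarnings(simulate_ordinal(cfg))
  st <- mgcfa_stats(d)
  cons <- list(equal_loadings = TRUE, equal_thresholds = TRUE,
               fix_psi2 = TRUE)
  fit <- fit_mgcfa_stats(st, estimator = "ULS", constraints = cons)

  disc <- function(l, t, a) {
    params <- list(lambda = rep(l, 3), tau = rep(list(t), 3),
                   alpha2 = a, psi2 = 1)
    latentdiff:::mgcfa_discrepancy(params, st)
  }
  coarse <- expand.grid(l = seq(0.05, 0.95, by = 0.05),
                        t = seq(-1, 1, by = 0.05),
                        a = seq(-1, 1, by = 0.05))
  coarse$f <- mapply(disc, coarse$l, coarse$t, coarse$a)
  best <- coarse[which.min(coarse$f), ]
  fine <- expand.grid(l = seq(best$l - 0.06, best$l + 0.06, by = 0.005),
                      t = seq(best$t - 0.06, best$t + 0.06, by = 0.005),
                      a = seq(best$a - 0.06, best$a + 0.06, by = 0.005))
  fine$f <- mapply(disc, fine$l, fine$t, fine$a)
  bestf <- fine[which.min(fine$f), ]

  expect_lte(fit$discrepancy, min(fine$f) + 1e-8)
  expect_lt(abs(unname(fit$lambda[1]) - bestf$l), 0.0075)
  expect_lt(abs(unname(fit$tau[[1]][1]) - bestf$t), 0.0075)
  expect_lt(abs(fit$alpha2 - bestf$a), 0.0075)
})

test_that("tidy and glance expose the fitted parameters coherently", {
  st <- population_stats(rep(0.7, 4), qnorm(c(0.25, 0.5, 0.75)),
                         alpha2 = 0.3, psi2 = 1)
  fit <- fit_mgcfa_stats(st, estimator = "ULS")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(td$estimate[td$term == "alpha2"], fit$alpha2)
  gl <- glance(fit)
  expect_equal(gl$omega, mcdonald_omega(fit))
  expect_equal(gl$latent_d, latent_d(fit))
})
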