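test_that("Cohen's d uses the pooled-SD, group-1-minus-group-2 convention", {
  d <- cohens_d(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))
  expect_equal(d$d, -2)
  expect_equal(d$n1, 3L)
  # identical distributions -> 0
  expect_equal(cohens_d(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$d, 0)
  # scale invariance: sum- vs mean-scoring cannot change d
  x <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  expect_equal(cohens_d(10 * x, g)$d, cohens_d(x, g)$d, tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 10), rep(c("a", "b"), 5)), "zero")
  expect_error(cohens_d(1:3, c("a", "a", "b")), "at least 2")
  expect_error(cohens_d(1:6, rep(c("a", "b", "c"), 2)), "two groups")
})

test_that("the d sampling variance matches its closed form", {
  expect_equal(d_variance(0, 50, 50), 2 / 50)
  expect_equal(d_variance(0.5, 100, 100), 0.020625)
  expect_equal(d_variance(1, 2, 2), 1.125)
  expect_equal(d_variance(0.3, 40, 160), d_variance(0.3, 160, 40))
  expect_gt(d_variance(0.8, 50, 50), d_variance(0.2, 50, 50))
  expect_error(d_variance(0.5, 1, 100), ">= 2")
})

test_that("discrepancy statistics reproduce printed per-scale rows", {
  # Tension: d_tau -0.151, d_Y -0.095
  tension <- compare_ds(effect_estimate(-0.151, 1000, 1000),
                        effect_estimate(-0.095, 1000, 1000))
  expect_equal(tension$delta_d, 0.056, tolerance = 1e-12)
  expect_equal(tension$signed_delta_d, 0.056, tolerance = 1e-12)
  # Warmth: both negative yet the signed discrepancy is positive
  warmth <- compare_ds(effect_estimate(-0.292, 1000, 1000),
                       effect_estimate(-0.288, 1000, 1000))
  expect_equal(warmth$signed_delta_d, 0.004, tolerance = 1e-12)
  expect_equal(round(warmth$signed_pct_change, 1), 1.4)
  # further printed rows: |d_tau| - |d_Y| equals the signed discrepancy
  rows <- tibble::tribble(
    ~d_tau, ~d_y,  ~signed,
    0.454,  0.353,  0.101,   # Reasoning
    -0.128, -0.211, -0.083,  # ECR Avoidant
    0.226,  0.151,  0.075,   # Openness to change
    0.863,  1.042, -0.179    # OSRI Masculine (printed 0.180 via rounding)
  )
  for (i in seq_len(nrow(rows))) {
    cmp <- compare_ds(effect_estimate(rows$d_tau[i], 500, 500),
                      effect_estimate(rows$d_y[i], 500, 500))
    expect_equal(cmp$signed_delta_d, rows$signed[i], tolerance = 5e-4)
  }
  # percent change uses the mean-of-magnitudes denominator
  reasoning <- compare_ds(effect_estimate(0.454, 500, 500),
                          effect_estimate(0.353, 500, 500))
  expect_equal(reasoning$pct_change, 100 * 0.101 / 0.4035, tolerance = 1e-10)
})

test_that("no discrepancy means z = 0 and p = 0.5; zero effects give NA percent", {
  same <- compare_ds(effect_estimate(0.3, 200, 200),
                     effect_estimate(0.3, 200, 200))
  expect_equal(same$delta_d, 0)
  expect_equal(same$z, 0)
  expect_equal(same$p, 0.5)
  zero <- compare_ds(effect_estimate(0, 200, 200), effect_estimate(0, 200, 200))
  expect_true(is.na(zero$pct_change))
  expect_true(is.na(zero$signed_pct_change))
})

test_that("swapping and negating effects transform the statistics correctly", {
  a <- effect_estimate(0.42, 300, 280)
  b <- effect_estimate(-0.17, 300, 280)
  ab <- compare_ds(a, b)
  ba <- compare_ds(b, a)
  expect_equal(ba$signed_delta_d, -ab$signed_delta_d)
  expect_equal(ba$delta_d, ab$delta_d)
  # relabeling groups negates both d's and changes nothing
  neg <- compare_ds(effect_estimate(-0.42, 300, 280),
                    effect_estimate(0.17, 300, 280))
  for (col in c("delta_d", "signed_delta_d", "pct_change",
                "signed_pct_change", "z", "p", "ci_low", "ci_high")) {
    expect_equal(neg[[col]], ab[[col]])
  }
})

test_that("the confidence interval is centered on the signed discrepancy", {
  cmp <- compare_ds(effect_estimate(0.5, 150, 150),
                    effect_estimate(0.3, 150, 150))
  se <- sqrt(cmp$var_d_tau + cmp$var_d_y)
  expect_equal(cmp$ci_low, cmp$signed_delta_d - qnorm(0.975) * se)
  expect_equal(cmp$ci_high, cmp$signed_delta_d + qnorm(0.975) * se)
})

test_that("compare_groups runs the full per-scale pipeline", {
  cfg <- ordinal_config(n_items = 5, loadings = 0.7,
                        n_per_group = c(1500, 1500), latent_d = 0.4,
                        seed = 61)
  d <- simulate_ordinal(cfg)
  sdef <- config_scale_def(cfg, name = "demo")
  row <- compare_groups(d, sdef, estimator = "ULS")
  expect_equal(row$scale, "demo")
  expect_equal(abs(row$d_tau), 0.4, tolerance = 0.08)
  expect_lt(abs(row$d_y), abs(row$d_tau))         # attenuation
  expect_equal(row$omega, implied_omega(cfg), tolerance = 0.04)
  expect_equal(row$n1, 1500L)
})

test_that("reverse-keyed items are unkeyed before scoring and fitting", {
  cfg <- ordinal_config(n_items = 4, loadings = 0.7,
                        n_per_group = c(1200, 1200), latent_d = 0.4,
                        seed = 62)
  d <- simulate_ordinal(cfg)
  flipped <- d
  flipped$item02 <- 4L - flipped$item02
  sdef_plain <- config_scale_def(cfg, name = "plain")
  sdef_rev <- scale_def(sdef_plain$items, reverse_keyed = "item02",
                        n_categories = 5, name = "rev")
  plain <- compare_groups(d, sdef_plain, estimator = "ULS")
  rev <- compare_groups(flipped, sdef_rev, estimator = "ULS")
  expect_equal(rev$d_y, plain$d_y, tolerance = 1e-10)
  expect_equal(rev$d_tau, plain$d_tau, tolerance = 1e-6)
})
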