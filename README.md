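# latentdiff

Measurement error makes observed questionnaire scores noisier than the
constructs they measure, and that noise inflates the denominator of every
standardized statistic computed from them. For a two-group comparison the
consequence is exact: under classical test theory
(X = τ + ε, σ²_X = σ²_τ + σ²_ε) the observed Cohen's d is

    d_observed = d_true · √reliability,

a shrinkage of 100·(1 − √reliability) percent — already more than 10% at a
reliability of 0.80. `latentdiff` is for psychometricians and applied
researchers who want to know how much this matters for their scales. It
compares, per scale,

* **d_Y** — Cohen's d on the observed sum/mean score
  ((μ₁ − μ₂)/SD_pooled), and
* **d_τ** — the standardized latent mean difference from a two-group
  ordinal one-factor model with thresholds and loadings constrained equal
  across groups (margin-based thresholds, two-step polychoric
  correlations, diagonally weighted or unweighted least squares, delta
  parameterization),

then forms the discrepancy |d_τ| − |d_Y| with a one-tailed z test (both
sampling variances from σ²_d = (n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂))),
McDonald's ω per scale, and a random-effects meta-analysis of the
discrepancies across scales (REML or DerSimonian–Laird, Q, I², τ), plus
the expected share of scales beyond a discrepancy cutoff and the
correlation between ω and the discrepancy.

Because raw questionnaire archives are not a dependency, the package
ships a synthetic-data module (`ordinal_config()`, `simulate_ordinal()`)
that generates two-group Likert-type data with known loadings,
thresholds, latent mean difference, group-2 variance, and implied ω —
every estimator is testable against ground truth.

## Worked example

Closed-form attenuation for a true d of 1 (true mean difference and
true-score variance both 1):

```r
library(latentdiff)
attenuation_table(digits = 2)
#>   reliability error_variance observed_variance observed_d
#> 1        1              0                 1          1
#> 2        0.9            0.11              1.11       0.95
#> 3        0.8            0.25              1.25       0.89
#> 4        0.7            0.43              1.43       0.84
#> 5        0.6            0.67              1.67       0.77
#> 6        0.5            1                 2          0.71
relative_bias_pct(0.80)
#> [1] 10.55728
```

Three simulated 6-item scales with decreasing reliability, all with a
true latent difference of 0.4 SD, 3000 respondents per group:

```r
scales <- lapply(c(0.75, 0.85, 0.92), function(om) {
  list(name = sprintf("omega%.2f", om),
       config = ordinal_config(n_items = 6,
                               loadings = sqrt(om / (6 - 5 * om)),
                               n_per_group = c(3000, 3000),
                               latent_d = 0.4))
})
study <- run_study(scales, estimator = "ULS", seed = 42)
dplyr::select(study$comparisons, scale, d_tau, d_y, signed_delta_d,
              pct_change, p, omega)
#>   scale      d_tau    d_y signed_delta_d pct_change      p omega
#> 1 omega0.75 -0.387 -0.327         0.0600      16.8  0.0517 0.752
#> 2 omega0.85 -0.400 -0.361         0.0390      10.3  0.145  0.845
#> 3 omega0.92 -0.428 -0.399         0.0286       6.92 0.219  0.919
```

Reading one row: for the ω ≈ 0.75 scale the observed comparison gives
−0.327 SD while the latent model, which excises measurement error,
gives −0.387 SD — the sum score understates the group difference by
0.060 SD, about 17% of the effect, and the understatement grows as
reliability falls (the recovered `omega` column tracks the generating
values). `glance(study)` pools the discrepancies across scales
(here 0.043 [0.001, 0.084] with no between-scale heterogeneity at k = 3),
and with pooled estimate 0.028 and between-scale SD 0.074 on the signed
scale,

```r
exceedance_probability(0.028, 0.074, 0.200)
#> [1] 1.005406
```

about 1% of scales are expected to show discrepancies beyond 0.2 SD.
`autoplot(study)` draws latent versus observed d with ±0.1 SD agreement
bands; `plot_discrepancies(study)` is the per-scale forest plot.

Scales whose fit is improper (a Heywood condition: non-positive residual
variance) are excluded from the study with the reason recorded in
`study$excluded`, and the run continues.

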