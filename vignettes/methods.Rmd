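---
title: "Observed versus latent group differences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observed versus latent group differences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentdiff)
```

## The problem

Questionnaire scales are scored by summing or averaging item responses, and
group differences on those scores are routinely standardized as Cohen's
$d$. Under classical test theory the observed score is true score plus
uncorrelated error, $X = \tau + \varepsilon$, so its variance decomposes as
$\sigma^2_X = \sigma^2_\tau + \sigma^2_\varepsilon$. The mean difference
between two groups is untouched by error, but the standardizing denominator
is inflated: with reliability $\rho = \sigma^2_\tau/\sigma^2_X$,

$$d_\text{observed} = d_\text{true}\,\sqrt{\rho},$$

a shrinkage of $100(1-\sqrt{\rho})$ percent. At $\rho = 0.80$ the bias
already exceeds 10%, which is why the package treats 0.80 as the reference
point below which a latent-variable comparison is strongly advisable
(`relative_bias_pct(0.80)` is 10.56). `attenuation_table()` tabulates the
exact consequences for a unit true difference and unit true variance.

The package quantifies this distortion for ordinal (Likert-type) scales by
comparing two estimates per scale:

* $d_Y$ — Cohen's $d$ on the observed sum (or mean) score, pooled-SD
  denominator;
* $d_\tau$ — the standardized latent mean difference from a two-group
  ordinal confirmatory factor model in which thresholds and loadings are
  constrained equal across groups,

and then aggregates the per-scale discrepancies by random-effects
meta-analysis.

## The ordinal factor model and its estimation

Each scale is modeled as unidimensional and congeneric: item $i$'s latent
response is $y^*_i = \lambda_i \eta + \varepsilon_i$, and the observed
category counts the thresholds $\tau_{ik}$ lying below $y^*_i$. Estimation
is the standard two-stage least-squares approach for ordinal data:

1. **Input statistics per group.** Thresholds from the inverse-normal of
   cumulative category proportions; pairwise polychoric correlations by
   two-step maximum likelihood (thresholds fixed at their margin
   estimates, the bivariate-normal likelihood maximized over $\rho$ on
   $[-0.999, 0.999]$, estimates at the bound clamped and flagged). The
   two-step estimator matches common WLSMV pipelines and differs
   negligibly from full joint ML at the sample sizes the package targets.
2. **Discrepancy minimization.** The fitter minimizes
   $\sum_g w_g^\top (s_g - \sigma_g(\theta))^2$ where $s_g$ stacks group
   $g$'s thresholds and polychoric correlations and $\sigma_g(\theta)$
   their model-implied counterparts. `estimator = "ULS"` uses identity
   weights (group terms weighted by group size); `estimator = "DWLS"`
   weights each statistic by the inverse of its grouped-jackknife variance
   (10 blocks per group by default, blocks assigned cyclically so the
   procedure is deterministic). Point estimates are consistent under
   either; the package does not compute mean-and-variance-adjusted test
   statistics, since no fit indices are consumed downstream.

**Identification (delta parameterization).** Group 1's latent trait is
standard normal and its latent item responses have unit variance, so
$\theta_i = 1 - \lambda_i^2$; thresholds apply directly on that scale.
Group 2 shares loadings and thresholds; its latent mean $\alpha_2$ and
variance $\psi_2$ are free, and its latent-response scale
$\sqrt{\lambda_i^2\psi_2 + \theta_i}$ follows from them. Item intercepts
are fixed at zero in both groups: for ordinal items the thresholds carry
all location information, so intercept equality holds by construction.
This mirrors the usual identification for latent mean comparison under
scalar invariance.

**Latent effect size.** $d_\tau = (\alpha_1 - \alpha_2)/\text{SD}_\text{pooled}$
with $\alpha_1 = 0$ and
$\text{SD}_\text{pooled} = \sqrt{((n_1-1)\cdot 1 + (n_2-1)\psi_2)/(n_1+n_2-2)}$.
The $(n-1)$ weighting mirrors the classical pooling in Cohen's $d$'s
denominator; the convention (group 1 minus group 2) matches the observed
$d_Y$, whose "group 1" is the first group level in sorted order.

**Reliability.** McDonald's $\omega$ is computed on the latent-response
scale of the constrained model,
$\omega = (\Sigma\lambda)^2\bar\psi / ((\Sigma\lambda)^2\bar\psi +
\Sigma\theta)$, with $\bar\psi$ the sample-size-weighted pooled latent
variance. Computing $\omega$ from the constrained (rather than
configural) model and on the latent-response (rather than categorical)
scale is a documented package convention; the two coincide in the
invariant, equal-variance populations the generator produces.

**Improper solutions.** A loading pushed to the boundary (implied residual
variance $1-\lambda^2 \le 0.002$) raises a classed Heywood error naming
the items; `run_study()` catches it, excludes the scale, records the
reason, and continues — the same treatment an applied analysis gives a
scale with negative error variance.

**Numerics.** The bivariate normal CDF is evaluated by Gauss–Legendre
quadrature of $\int \phi(x)\Phi((b-\rho x)/\sqrt{1-\rho^2})\,dx$ on three
segments split around $x = b/\rho$, accurate to about $10^{-9}$ across the
admissible $\rho$ range (the test suite cross-checks against an
independent implementation). The $\rho$ search uses Brent's method with
tolerance $10^{-6}$; empty cells contribute zero to the log-likelihood (no
continuity correction), the simplest defensible convention. The model
optimizer is BFGS on transformed parameters ($\mathrm{atanh}\,\lambda$,
$\log \psi_2$, first threshold plus log-gaps so threshold order is
maintained), relative tolerance $10^{-10}$, at most 500 iterations.
Starting values are deterministic: $\lambda$ from the first principal
axis of the pooled polychoric matrix (sign aligned to a positive sum),
thresholds from pooled margins, $\alpha_2$ from the average
loading-scaled threshold shift, $\psi_2 = 1$.

## Discrepancy statistics

For one scale, with sampling variances from the Choi–Lam formula
$\sigma^2_d = (n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))$:

* signed discrepancy $= |d_\tau| - |d_Y|$ — the difference of
  *magnitudes*, positive when excising error enlarges the effect. Working
  with magnitudes makes the statistic invariant to relabeling the groups.
* $\Delta d$ = its absolute value; percent change uses the symmetric
  mean-of-magnitudes denominator $(|d_\tau|+|d_Y|)/2$, with the sign of
  the signed discrepancy attached for the signed version. Both effects
  exactly zero leaves percent change undefined (`NA`), never zero.
* $z$ = signed discrepancy over $\sqrt{\sigma^2_{d_\tau} +
  \sigma^2_{d_Y}}$. The two estimates share a sample and are positively
  dependent, so treating them as independent overstates the variance of
  their difference; the one-tailed test (alternative: the latent effect is
  larger in magnitude, as attenuation predicts) is therefore conservative.
* the 95% interval is centered on the signed discrepancy,
  $\pm 1.96\,\text{SE}$ — a deliberate, simple convention, recorded here
  because interval construction for such differences is underdetermined
  in common practice.

## Meta-analysis

`random_effects_meta()` delegates to `metafor::rma()` (REML by default,
DerSimonian–Laird available), with Cochran's $Q$ on fixed-effect weights
and the usual $I^2$. Each scale's within-variance is
$\sigma^2_{d_\tau}+\sigma^2_{d_Y}$, consistent with the $z$ test.
`exceedance_probability()` reads the random-effects model literally — true
scale discrepancies $\sim N(\hat\mu, \hat\tau^2)$ — and reports the
percent of scales expected beyond a cutoff. The
reliability–discrepancy association is available as Pearson or Spearman
via `omega_discrepancy_cor()`, both with Fisher-$z$ intervals (for
Spearman this is the common large-sample approximation applied to the
rank correlation, and ties are handled by the asymptotic p-value).

## What the generator emulates — and what it does not

`simulate_ordinal()` draws two groups from exactly the model the fitter
assumes: unidimensional congeneric structure, identical loadings and
thresholds across groups (exact scalar invariance), complete data, and a
known latent mean difference and group-2 variance. Defaults are chosen to
mimic Likert questionnaires: 5 response categories with thresholds at
standard-normal quantiles of equal quintiles, loadings 0.7, 1000
respondents per group. `latent_d` is expressed on group 1's SD scale when
$\psi_2 = 1$ and on the pooled latent SD scale otherwise, so recovery
targets are unambiguous. One integer seed drives a single RNG stream
consumed group 1 first, then group 2; identical seeds give byte-identical
data.

Passing recovery tests under this generator shows that the estimators are
consistent and essentially unbiased *when the model holds*. It says
nothing about violated invariance (differential item functioning),
correlated residuals, acquiescence or social desirability, multi-factor
structure, or missingness — all deliberately outside the package's scope.
Real questionnaire analyses can violate each of these; the package's own
framing is that invariance is equally presumed by the sum score, so the
comparison remains apples-to-apples.

An analytic caveat for the end-to-end attenuation check: the prediction
$(1-\sqrt{\omega})|d|$ uses $\omega$ on the *latent-response* scale,
while the observed sum score is additionally coarsened by
categorization. With 5 quintile categories the per-item
category–latent-response correlation is about 0.94
($\sum_k \phi(t_k)/\sqrt{\mathrm{Var}(X)} = 1.333/\sqrt{2}$), which adds
roughly 0.005 to the expected discrepancy at $d = 0.3$ for six items with
loadings 0.7. The test tolerance of 0.02 on the mean across scales was
set from this calculation plus the Monte-Carlo standard error
(about 0.004), before running the check.

## Problem sizes

The test suite and the acceptance script work at desk scale, chosen so the
full run completes in a few minutes on one core while keeping Monte-Carlo
error well inside the assertion tolerances: continuous attenuation checks
at $10^5$ per group; threshold recovery at $5\times 10^4$; polychoric
recovery at $5\,000$; factor-model recovery at $2\,000$–$5\,000$ per group
(20 replicates for the bias check, per-fit Monte-Carlo SD about 0.036);
the end-to-end study with five scales of $3\,000$ per group spanning
$\omega$ from 0.70 to 0.94; meta-analysis calibration with $k = 70$
scales. Brute-force oracles (a likelihood grid at step $10^{-4}$ for the
2×2 polychoric; a coarse-to-fine discrepancy grid for a three-binary-item
constrained model) confirm that the optimizers find the same minima.

## Known limitations

* Single-factor models only; scales that are in truth multidimensional
  must be split into subscales by the caller.
* No model fit indices; the package reports parameters, not fit.
* The DWLS weights are jackknife approximations to the asymptotic
  variances of the input statistics, not the full WLSMV weight matrix;
  they affect efficiency, not consistency.
* The Spearman confidence interval is an approximation; exact small-sample
  inference for rank correlations is not attempted.
* `exceedance_probability()` inherits the normality of the random-effects
  model; heavy-tailed between-scale distributions will be misrepresented.
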