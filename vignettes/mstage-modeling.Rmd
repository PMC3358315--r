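---
title: "Multistage frailty modeling of cancer incidence age patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage frailty modeling of cancer incidence age patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstagefrailty)
```

## The model

Registry incidence rates of most adult carcinomas rise steeply with age as a
power law, then decelerate and often decline past ages 80–85. The model at
the core of this package explains both features with two ingredients:

1. **A multistage (Weibull) baseline.** An individual must pass `m`
   rate-limiting stages ("m-stages") before a tumor is clinically
   diagnosed. With independent transitions this gives the individual hazard
   \[
   \mu_0(x) = \frac{m}{c}\left(\frac{x}{c}\right)^{m-1},
   \]
   the continuous analogue of the Armitage–Doll multistage incidence law.
   `m` is the Weibull shape (the log–log slope of the rising limb plus one)
   and `c` is an age scale in years.

2. **Frailty: heterogeneity in predisposition.** Individuals differ in
   susceptibility by an unobserved multiplicative factor `z` with mean 1 and
   variance `sigma^2`, drawn from a power-variance family indexed by `n`
   (`n = 1` gamma, `n = 2` inverse Gaussian, `n -> 0` an
   exponential-attenuation limit). High-frailty individuals are diagnosed
   early, so the surviving population is progressively selected for low
   frailty and the *population* rate bends away from the baseline:
   \[
   \lambda(x) = \frac{m}{c}\left(\frac{x}{c}\right)^{m-1}
   \Bigl[1 + n\,\sigma^2\,(x/c)^m\Bigr]^{-1/n},
   \]
   with limit \(\mu_0(x)\exp(-\sigma^2 (x/c)^m)\) as \(n \to 0\). Setting
   `sigma = 0` recovers the homogeneous Weibull/Armitage–Doll law exactly.

For `m > 1`, `sigma > 0` and `m - n(m-1) > 0` the rate has an interior
maximum at

\[
x^\ast = c\left[\frac{m-1}{\sigma^2\,(m - n(m-1))}\right]^{1/m}
\]

(`mode_age()`), followed by a strictly decreasing tail — the late-age
downturn. When `m - n(m-1) <= 0` the rate is monotone and `mode_age()`
returns `NA`.

Covariates enter proportionally (`model2_rate()`): relative risks `r_sex`
(females vs males) and `r_race` (African-Americans vs Caucasians), and a
parametric period trend \((1 + F_{year}/100)^{(year - year_0)/10}\), the
percent change per decade anchored at `ref_year` (default 1988, the midpoint
of a 1973–2003 observation window).

### What `m` is, and is not

`m` counts rate-limiting transitions of a *person* toward diagnosis; several
molecular events may occur within one m-stage, and the parameter is not the
mutation count of clonal-expansion models (TSCE/MSCE), whose hazards this
package deliberately does not implement. The package's scientific use case
is comparative: estimating `m` per cancer site and histotype
(adenocarcinoma vs squamous cell carcinoma) and asking whether histotype or
organ drives the differences.

### Parameterization choices

Published per-cancer tables sometimes describe `c` loosely as the age of
peak incidence. We treat `c` throughout as the Weibull age-scale parameter:
the mapping between the two conventions depends on `(m, sigma, n)` through
the mode formula, and `m` — the quantity of scientific interest — is
invariant to this choice. The two uterine adenocarcinoma parameter rows are stored
with the assignment that is consistent with the published per-organ
comparisons and subgroup means (the tightly determined row, m = 8.80, as
cervical; the weakly determined row, m = 8.42, as corpus); see the
package's source notes. The numerically stable form
`exp(-log1p(n * sigma^2 * u)/n)` evaluates the frailty attenuation for all
`n` down to `1e-12`, below which the exponential limit branch is used; the
two branches agree to better than `1e-6` relative error at the crossover.

## Data model and weighting

Incidence panels are long-format tables of (age, year, sex, race) cells
with diagnosis counts and person-years (`incidence_table()`); ages are
1-year bins evaluated at midpoints (`age + 0.5`). Each cancer has a
minimum analysis age below which registry cases are too sparse (30 years
for most adenocarcinomas, 15 for most squamous sites, 20 for ductal breast,
25 for ovary, 40 for prostate); the open-ended 85+ bin is excluded by
default (`filter_min_age()`).

Weighted fitting needs a variance for every cell, including zero-count
ones. `rate_and_variance()` uses the Wilson score-interval variance of a
binomial proportion,
\(\tilde p (1-\tilde p)/(N + z^2)\) with
\(\tilde p = (k + z^2/2)/(N + z^2)\), which stays strictly positive at
`k = 0`; `z = 1.96` by default (the level is not critical and is
configurable). Weights are the reciprocal variances.

One refinement matters in low-count panels: weights computed from
*observed* counts are correlated with the sampling errors of the rates
(cells that fluctuate low get too much weight), which biases the fitted
shape upward — about +0.5 stages for an esophageal-SCC-like generator at
2e5 person-years per cell in our simulations. `fit_config(reweight = 1)`
(the default) therefore re-derives the Wilson variances from the fitted
expected counts after the first optimization pass and re-polishes the fit;
this removed the bias in parameter-recovery runs (errors under 0.15 stages
for the panels in `scripts/acceptance.R`) while keeping the Wilson form.

## Estimation

`fit_model1()` fits `(m, c, sigma, n)` to a pooled single age pattern;
`fit_model2()` fits the covariate generalization jointly over all cells of
a panel (for a 30–84 age range over 1973–2003 and 2 sexes x 2 races, 6820
cells). Two objectives are available:

* `wnls` — weighted nonlinear least squares on rates (the default), and
* `mle` — Poisson maximum likelihood on counts, used as a cross-check
  (sensitivity scenario `mle_vs_wnls`).

The objective is multimodal in `(sigma, n)`, so optimization uses bounded
L-BFGS-B restarted from a data-driven initial point (`m` from the log–log
slope of the rising limb plus one, `c` from the empirical rate maximum,
`sigma = 1`, `n = 1`, relative risks from exposure-weighted rate ratios,
trend from a log-linear year regression) plus Latin-hypercube draws within
the bounds (default 8 starts; identical seeds give bit-identical results).
The best run by objective — ties broken toward smaller `m` — is re-polished
once. Default bounds: `m` in [1, 30], `c` in [10, 250] years, `sigma` in
[0, 400], `n` in [0, 3] (`n` is fitted freely rather than selected from
{0, 1, 2}, since non-integer shapes fit many sites best), relative risks in
[0.01, 10], `f_year` in [-90, 400] percent.

Standard errors come from the curvature at the optimum: for WNLS the
Jacobian cross-product scaled by the residual \(\chi^2/\mathrm{dof}\) (with
one-sided finite differences at active bounds, e.g. `sigma = 0`); for MLE
the inverse observed information. Fit quality is \(\chi^2/\mathrm{dof}\)
(`goodness_of_fit()`), and `residual_diagnostics()` screens weighted
residuals for normality (moment-based omnibus test), heteroscedasticity
(rank correlation of squared residuals with fitted values) and
autocorrelation (Durbin–Watson over age ordering). `compare_models()` ranks
the frailty model against the homogeneous Armitage–Doll/Weibull laws and
reports nested F-tests on the weighted residual sums.

Parameters whose covariate does not vary in the panel (e.g. `r_sex` in a
single-sex cancer) are automatically held at their reference value and
flagged, mirroring how sex-specific sites are reported with a relative risk
of exactly 1.

### Identifiability limits worth knowing

For very large frailty variance the observable age range may lie entirely
beyond the mode, where the rate is close to a pure power law with exponent
\(m - 1 - m/n\): only that combination is then well determined, and `m`
itself has enormous uncertainty. The bundled corpus-uteri row
(`sigma = 100.5`) is of this kind — its `m` recoveries scatter widely with
correspondingly large reported SEs. This is a property of the model and
data, not of the optimizer; treat `m` estimates with SEs above ~1 stage as
boundary cases.

## Age-period-cohort embedding

The single-parameter period trend cannot represent arbitrary secular
structure, so `fit_apc()` replaces it by nonparametric multipliers on
10-year birth-cohort bins and 5-year calendar-period bins (a trailing
short bin is merged, e.g. 1998–2003), estimated on the log scale to enforce
positivity. Rescaling all cohort effects by `k` and all period effects by
`1/k` leaves rates unchanged, so the bins containing the panel midpoint are
fixed at exactly 1; with the parametric age curve this normalization makes
the solution unique (verified by refitting from random starts). The
parametric `f_year` is removed — not co-estimated — in APC fits to avoid
confounding with the period multipliers. The scientific use is a stability
check: on panels without generated secular structure the APC and
parametric fits should agree on `m` to well within 1.5 stages.

## The synthetic registry generator

`simulate_panel()` draws Poisson counts around `person_years x rate` for
every cell of a specified panel; at registry rates (well below one event
per person-year) Poisson and binomial sampling are indistinguishable, and
Poisson matches the MLE objective. Defaults emulate the structure of a
SEER-like extract: 1-year ages from the cancer's minimum age to 84, 31
calendar years (1973–2003), two sexes, two races, and a constant
2e5 person-years per cell (the exposure model accepts a function of age
and stratum for registry-thinning experiments). `build_panel_library()`
yields one generator per bundled parameter row — 14 adenocarcinomas and 12
squamous cell carcinomas with the printed values as generating truth.

What the generator deliberately does **not** emulate: real population
pyramids and registry coverage changes, stage-at-diagnosis coding shifts,
within-cell overdispersion, and secular structure beyond the model's own
covariate terms. Passing recovery tests therefore shows that the estimation
machinery is correct and calibrated under the model's own assumptions — not
that the model is correct for any particular real registry series.

`simulate_stage_table()` produces stage-at-diagnosis distributions (in
situ/localized/regional/distant/unstaged percentages) drifting linearly
over years, clipped and renormalized, for exercising the stage-correlation
analysis; `redistribute_unstaged()` reallocates unstaged mass
proportionally across staged categories.

## The histotype analysis

`group_summary()` computes per-histotype means of `m` with standard errors
of the mean (sample SD, `n - 1` denominator); the non-reproductive
adenocarcinoma subgroup excludes by default the two breast rows, ovary,
cervix and prostate. `compare_histotypes()` applies a normal z-test
treating group SEs as known — appropriate when only summary estimates, not
case-level data, are available. `correlate_mstages_stage()` relates `m`
estimates to stage-at-diagnosis fractions (unweighted mean over available
years per cancer — the averaging rule is a package convention) by Pearson
correlation with a t-transform p-value. `sensitivity_suite()` bundles the
seven protocol perturbations (minimum-age shift, 85+ inclusion, quadratic
trend term, 5-year age bins, MLE vs WNLS, period restriction, APC
embedding) and reports the shift in `m` for each.

## Problem sizes used by the test suite

The package's tests and acceptance runs use these simulation scales, chosen
to exercise every claim at desk scale: parameter-recovery runs on full
6820-cell panels at 2e5 person-years per cell with 8 optimizer starts;
calibration of \(\chi^2/\mathrm{dof}\), SE coverage and the F-test type-I
rate on 100 single-pattern replicates (55 age points each); the 26-panel
library fitted once per row with fixed seeds; APC stability on 20
structure-less replicates. Quadrature oracles (gamma and inverse-Gaussian
mixtures) verify the closed-form hazard to 1e-6 relative error.

## A worked example

```{r example, eval = FALSE}
library(mstagefrailty)

# generating truth: the printed lung adenocarcinoma row
row <- subset(seer_cancer_parameters(), cancer == "lung_ac")
spec <- spec_from_parameters(row, seed = 101)
panel <- simulate_panel(spec)

fit <- fit_model2(panel, fit_config(multistart = 8, seed = 11))
fit
#> model2 fit (wnls), 6820 points, chi2/dof = 0.968, converged: TRUE
#>               m       c  sigma      n  r_sex r_race  f_year
#> estimate 9.7837 83.8903 9.3912 0.6493 0.6393 0.8906 33.0449
#> se       0.0299  0.1365 0.0269 0.0023 0.0017 0.0023  0.1980

mode_age(frailty_weibull_params(fit$estimates[["m"]], fit$estimates[["c"]],
                                fit$estimates[["sigma"]], fit$estimates[["n"]]))
```

## Known limitations

* The frailty distribution is identified only through the shape of the
  population rate; different `(sigma, n)` pairs can be nearly
  observationally equivalent, and `m` inherits that uncertainty when the
  mode lies below the minimum analysis age.
* Clonal-expansion (TSCE/MSCE) hazards, cure-rate and two-disease mixture
  models are out of scope.
* SEs are curvature-based; no bootstrap intervals are provided.
* The z-test for group comparisons ignores uncertainty in the group SEs
  themselves (adequate for groups of 9–14 cancers, anti-conservative for
  much smaller groups).
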