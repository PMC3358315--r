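# mstagefrailty

Multistage frailty models for population cancer incidence age patterns.

## The scientific problem

Registry incidence rates of adult carcinomas rise with age roughly as a
power law and then, for most sites, decelerate and decline past ages 80–85.
Multistage carcinogenesis theory reads the power-law slope as the number of
rate-limiting transitions ("m-stages") an individual passes on the way to a
clinically diagnosed tumor; the late-age downturn is explained by hidden
heterogeneity in predisposition ("frailty"): highly susceptible individuals
are diagnosed early, so the surviving population is selected toward low
susceptibility.

This package implements that model family for registry-style incidence
panels and the comparative analysis it supports: do adenocarcinomas (ACs)
and squamous cell carcinomas (SCCs) of the same organs need different
numbers of m-stages?

The core incidence rate is a Weibull baseline marginalized over a
power-variance-family frailty `z` (mean 1, variance σ²):

    λ(x) = (m/c) (x/c)^(m−1) [1 + n σ² (x/c)^m]^(−1/n)

with the limit `λ(x) = (m/c)(x/c)^(m−1) exp(−σ²(x/c)^m)` as `n → 0`;
`n = 1` is gamma frailty, `n = 2` inverse Gaussian, `σ = 0` recovers the
homogeneous Armitage–Doll/Weibull law. Covariates act proportionally:
relative risks for sex and race and a percent-per-decade calendar trend,
optionally replaced by nonparametric birth-cohort and period multipliers
(an age-period-cohort embedding). Fitting is by weighted nonlinear least
squares with Wilson score-interval variance weights (finite even for
zero-count cells) or by Poisson maximum likelihood, with multistart bounded
quasi-Newton optimization.

Intended users: biostatisticians and cancer epidemiologists modeling
age-incidence curves from registry tables (counts + person-years), and
methodologists studying frailty-induced rate downturns.

## A worked example

Simulate a SEER-like panel (55 one-year age bins 30–84, 31 calendar years
1973–2003, 2 sexes × 2 races, 2×10⁵ person-years per cell) from the bundled
lung-adenocarcinoma parameter row, then refit it:

```r
library(mstagefrailty)

row  <- subset(seer_cancer_parameters(), cancer == "lung_ac")
spec <- spec_from_parameters(row, seed = 101)     # m = 9.79 generating truth
panel <- simulate_panel(spec)

fit <- fit_model2(panel, fit_config(multistart = 8, seed = 11))
fit
#> model2 fit (wnls), 6820 points, chi2/dof = 0.968, converged: TRUE
#>               m       c  sigma      n  r_sex r_race  f_year
#> estimate 9.7837 83.8903 9.3912 0.6493 0.6393 0.8906 33.0449
#> se       0.0299  0.1365 0.0269 0.0023 0.0017 0.0023  0.1980
```

The fitted `m` of 9.78 ± 0.03 recovers the generating number of m-stages;
`c` is the age scale in years, `sigma`/`n` describe the frailty
distribution (here close to gamma), `r_sex = 0.64` means female rates are
64% of male rates, and `f_year = 33.0` is a +33% incidence change per
decade. `chi2/dof ≈ 1` says the residuals are consistent with sampling
noise. The age of maximal incidence implied by the fit:

```r
mode_age(frailty_weibull_params(9.7837, 83.8903, 9.3912, 0.6493))
#> [1] 57.39799
```

Histotype summary over the bundled per-cancer estimates (no fitting):

```r
est <- with(seer_cancer_parameters(),
            data.frame(cancer, histotype, m, se = m_se))
group_summary(est)$group_stats
#>                group      mean        se  n
#> 1                SCC 10.500000 0.6066625 12
#> 2                 AC  9.323571 0.5146498 14
#> 3 AC_nonreproductive  9.047778 0.3217823  9
```

SCCs average 10.5 ± 0.6 m-stages against 9.3 ± 0.5 for ACs (9.0 ± 0.3 for
ACs of non-reproductive organs); `compare_histotypes()` formalizes the
difference as a z-test, `correlate_mstages_stage()` relates `m` to
stage-at-diagnosis fractions, and `sensitivity_suite()` re-estimates `m`
under seven protocol perturbations (minimum-age shift, 85+ inclusion,
quadratic trend, 5-year bins, MLE vs WNLS, period restriction, APC).

A thin command-line wrapper over the same functions is provided at
`inst/scripts/mstage-cli.R` (`simulate` / `fit` / `analyze` subcommands).

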