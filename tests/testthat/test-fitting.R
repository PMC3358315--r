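test_that("noise-free rates are recovered exactly with a vanishing objective", {
  for (p in list(lung_ac_params(),
                 frailty_weibull_params(11.41, 79.1, 7.3, 0.57))) {
    tab <- noise_free_pattern(p)
    fit <- fit_model1(tab, quick_cfg())
    expect_true(fit$converged)
    expect_lt(fit$chi2_dof, 1e-6)
    expect_equal(fit$estimates[["m"]], p$m, tolerance = 1e-4)
    expect_equal(fit$estimates[["c"]], p$c, tolerance = 1e-4)
    expect_equal(fit$estimates[["sigma"]], p$sigma, tolerance = 1e-3)
    # exact-fit residuals carry no information for diagnostics
    expect_false(fit$diagnostics$available)
  }
})

test_that("identical seed and configuration reproduce the fit bit for bit", {
  tab <- sim_pattern(lung_ac_params(), seed = 314)
  f1 <- fit_model1(tab, fit_config(multistart = 4, seed = 99))
  f2 <- fit_model1(tab, fit_config(multistart = 4, seed = 99))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$se, f2$se)
})

test_that("Weibull submodel recovery works with sigma held at zero", {
  p <- frailty_weibull_params(6, 120, 0, 1)
  cover_m <- 0; cover_c <- 0
  for (s in 1:10) {
    fit <- fit_model1(sim_pattern(p, seed = s),
                      quick_cfg(fix = c(sigma = 0, n = 1)))
    expect_true(fit$converged)
    expect_equal(fit$n_free, 2L)
    expect_equal(fit$se[["sigma"]], 0)  # fixed parameters report zero SE
    if (abs(fit$estimates[["m"]] - 6) <= 2 * fit$se[["m"]])
      cover_m <- cover_m + 1
    if (abs(fit$estimates[["c"]] - 120) <= 2 * fit$se[["c"]])
      cover_c <- cover_c + 1
  }
  # nominal-95% intervals: allow binomial slack over 10 replicates
  expect_gte(cover_m, 8)
  expect_gte(cover_c, 8)
})

test_that("goodness of fit is the weighted residual sum per dof", {
  tab <- sim_pattern(lung_ac_params(), seed = 21)
  fit <- fit_model1(tab, quick_cfg())
  expect_equal(goodness_of_fit(fit), fit$chi2_dof)
  expect_gt(fit$chi2_dof, 0)
  exact <- fit_model1(noise_free_pattern(lung_ac_params()), quick_cfg())
  expect_lt(goodness_of_fit(exact), 1e-6)
})

test_that("residual diagnostics flag autocorrelation and need enough points", {
  mk_fit <- function(resid) {
    n <- length(resid)
    df <- data.frame(age = seq_len(n) + 29, year = 1988, female = 0,
                     african_american = 0, rate = 1e-4 + resid * 1e-5,
                     w = 1e10, count = 1, person_years = 1e5)
    structure(list(data = df, fitted = rep(1e-4, n),
                   config = fit_config()), class = "mstage_fit")
  }
  # alternating-sign residuals push Durbin-Watson above 2
  alt <- mk_fit(rep(c(1, -1), 20))
  expect_gt(residual_diagnostics(alt)$autocorrelation_stat, 2)
  # white-noise residuals sit near 2 (DW sd ~ 2/sqrt(n) ~ 0.27 at n = 55)
  set.seed(8)
  dw <- replicate(20, residual_diagnostics(
    mk_fit(rnorm(55)))$autocorrelation_stat)
  expect_lt(abs(mean(dw) - 2), 0.2)
  expect_true(all(dw > 1.2 & dw < 2.8))
  # too few residuals: unavailable
  expect_false(residual_diagnostics(mk_fit(rnorm(10)))$available)
})

test_that("weighted least squares and Poisson likelihood agree at scale", {
  tab <- sim_pattern(lung_ac_params(), seed = 5, exposure = 1e6)
  fw <- fit_model1(tab, quick_cfg())
  fm <- fit_model1(tab, quick_cfg(method = "mle"))
  comb <- sqrt(fw$se[["m"]]^2 + fm$se[["m"]]^2)
  expect_lt(abs(fw$estimates[["m"]] - fm$estimates[["m"]]), 2 * comb)
})

test_that("the m estimator tightens when exposure grows 100-fold", {
  p <- lung_ac_params()
  err_at <- function(exposure) {
    median(abs(vapply(1:12, function(s) {
      fit_model1(sim_pattern(p, seed = 600 + s, exposure = exposure),
                 quick_cfg())$estimates[["m"]] - p$m
    }, numeric(1))))
  }
  expect_lt(err_at(2e6), err_at(2e4))
})

test_that("model comparison ranks the frailty model above homogeneous laws", {
  tab <- sim_pattern(lung_ac_params(), seed = 909)
  cmp <- compare_models(tab, config = quick_cfg())
  expect_equal(cmp$ranking$model[1], "frailty_weibull")
  expect_true(all(c("armitage_doll", "weibull") %in% cmp$tests$null_model))
  expect_true(all(cmp$tests$p_value < 0.05))   # strong downturn in the data
  # single candidate: ranking of length one, no nested tests
  solo <- compare_models(tab, "weibull", quick_cfg())
  expect_equal(nrow(solo$ranking), 1L)
  expect_null(solo$tests)
})

test_that("panel fits recover covariate effects and flag unidentifiable ones", {
  p <- lung_ac_params()
  cov <- covariate_params(r_sex = 0.64, r_race = 1.33, f_year = 0)
  spec <- cohort_spec(p, cov = cov, ages = 30:84, years = 1973:2003,
                      exposure = 2e5, seed = 77)
  panel <- simulate_panel(spec)
  expect_equal(nrow(panel), 55 * 31 * 4)       # 6820 cells
  fit <- fit_model2(panel, quick_cfg())
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["r_race"]] - 1.33),
            2 * fit$se[["r_race"]] + 1e-9)
  expect_lt(abs(fit$estimates[["f_year"]] - 0),
            2 * fit$se[["f_year"]] + 1e-9)
  # single-sex panel: r_sex held at 1 with a warning
  fem <- spec
  fem$strata <- data.frame(female = 1, african_american = 0:1)
  expect_warning(ffit <- fit_model2(simulate_panel(fem), quick_cfg()),
                 "single-sex")
  expect_equal(ffit$estimates[["r_sex"]], 1)
  expect_equal(ffit$se[["r_sex"]], 0)
})

test_that("degenerate inputs raise domain errors", {
  rec <- data.frame(age = 30:50, year = 1988, female = 0,
                    african_american = 0, count = 0, person_years = 1e5)
  expect_error(fit_model1(incidence_table(rec), quick_cfg()), "degenerate")
  few <- incidence_table(rec[1:5, ])
  expect_error(fit_model1(few, quick_cfg()), "at least 10")
})
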