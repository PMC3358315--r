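# shared fixtures: all synthetic inputs are generated in code

single_stratum <- data.frame(female = 0, african_american = 0)

quick_cfg <- function(...) fit_config(multistart = 3, seed = 7, ...)

lung_ac_params <- function() frailty_weibull_params(9.79, 83.8, 9.4, 0.65)

# one-stratum, one-year Poisson panel
sim_pattern <- function(params, seed, exposure = 2e5, ages = 30:84,
                        year = 1988) {
  simulate_panel(cohort_spec(params, ages = ages, years = year,
                             strata = single_stratum, exposure = exposure,
                             seed = seed))
}

# noiseless panel: counts set exactly to person_years x model rate
noise_free_pattern <- function(params, exposure = 2e5, ages = 30:84,
                               year = 1988) {
  lam <- frailty_marginal_hazard(ages + 0.5, params)
  incidence_table(
    data.frame(age = ages, year = year, female = 0, african_american = 0,
               count = lam * exposure, person_years = exposure),
    min_age = min(ages))
}

# frailty-mixture marginal hazard by numerical quadrature (independent oracle)
marginal_hazard_oracle <- function(x, m, c, sigma, family = c("gamma", "ig")) {
  family <- match.arg(family)
  mu0 <- (m / c) * (x / c)^(m - 1)
  M <- (x / c)^m
  if (family == "gamma") {
    dens <- function(z) stats::dgamma(z, shape = 1 / sigma^2, rate = 1 / sigma^2)
    upper <- stats::qgamma(1 - 1e-14, shape = 1 / sigma^2, rate = 1 / sigma^2)
  } else {
    lam <- 1 / sigma^2   # inverse Gaussian, mean 1, variance sigma^2
    dens <- function(z) sqrt(lam / (2 * pi * z^3)) * exp(-lam * (z - 1)^2 / (2 * z))
    upper <- 1 + 60 * sigma
  }
  # for a large cumulative baseline M the integrand mass sits near zero; a
  # finite upper limit keeps the adaptive rule from extrapolation trouble
  if (M > 1) upper <- min(upper, 80 / M + 1)
  quad <- function(f) {
    out <- tryCatch(
      stats::integrate(f, 0, upper, rel.tol = 1e-10, abs.tol = 0,
                       subdivisions = 400L),
      error = function(e)
        stats::integrate(f, 0, upper, rel.tol = 1e-8, abs.tol = 0,
                         subdivisions = 1000L))
    out$value
  }
  mu0 * quad(function(z) z * exp(-z * M) * dens(z)) /
    quad(function(z) exp(-z * M) * dens(z))
}
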