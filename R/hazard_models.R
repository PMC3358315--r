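#' Parameters of the frailty-Weibull incidence model
#'
#' Bundles the four baseline parameters of the marginal incidence-rate model:
#' the number of rate-limiting stages `m` (m-stages), the Weibull age scale
#' `c` (years), the standard deviation `sigma` of the frailty distribution
#' (individual predisposition to cancer, mean 1), and the power-variance-family
#' shape index `n` (`n = 1` gamma frailty, `n = 2` inverse-Gaussian frailty,
#' `n = 0` the exponential-attenuation limit).
#'
#' @param m number of m-stages; `m >= 1`. Equals the Weibull shape parameter
#'   of the baseline hazard.
#' @param c age-scale parameter in years; `c > 0`.
#' @param sigma standard deviation of the frailty distribution; `sigma >= 0`.
#'   `sigma = 0` removes heterogeneity and the model reduces exactly to the
#'   Weibull baseline.
#' @param n frailty-family shape index; `n >= 0`.
#' @return An object of class `frailty_weibull_params`.
#' @examples
#' p <- frailty_weibull_params(m = 9.79, c = 83.8, sigma = 9.4, n = 0.65)
#' frailty_marginal_hazard(50, p)
#' @export
frailty_weibull_params <- function(m, c, sigma = 0, n = 1) {
  for (v in list(m = m, c = c, sigma = sigma, n = n)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("all parameters must be finite scalars", call. = FALSE)
  }
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  if (c <= 0) stop("'c' must be positive", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  structure(list(m = m, c = c, sigma = sigma, n = n),
            class = "frailty_weibull_params")
}

#' @export
print.frailty_weibull_params <- function(x, ...) {
  cat(sprintf("frailty-Weibull parameters: m = %.4g, c = %.4g yr, sigma = %.4g, n = %.4g\n",
              x$m, x$c, x$sigma, x$n))
  invisible(x)
}

#' Covariate (relative-risk and period-trend) parameters
#'
#' @param r_sex relative risk of incidence for females (males are the
#'   reference); `r_sex > 0`.
#' @param r_race relative risk for African-Americans (Caucasians are the
#'   reference); `r_race > 0`.
#' @param f_year percent change in incidence rates per 10-year calendar
#'   period; `1 + f_year/100 > 0`.
#' @param ref_year calendar year at which the period trend factor equals 1.
#' @return An object of class `covariate_params`.
#' @export
covariate_params <- function(r_sex = 1, r_race = 1, f_year = 0,
                             ref_year = 1988L) {
  for (v in list(r_sex, r_race, f_year, ref_year)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("all covariate parameters must be finite scalars", call. = FALSE)
  }
  if (r_sex <= 0 || r_race <= 0)
    stop("relative risks must be positive", call. = FALSE)
  if (1 + f_year / 100 <= 0)
    stop("'f_year' must satisfy 1 + f_year/100 > 0", call. = FALSE)
  structure(list(r_sex = r_sex, r_race = r_race, f_year = f_year,
                 ref_year = as.integer(ref_year)),
            class = "covariate_params")
}

#' Covariate profile of a population stratum
#'
#' @param female 0/1 indicator (1 = female); vectorized.
#' @param african_american 0/1 indicator (1 = African-American); vectorized.
#' @param year calendar year; vectorized.
#' @return A list of class `covariate_profile` with recycled components.
#' @export
covariate_profile <- function(female = 0, african_american = 0, year = 1988L) {
  if (!all(female %in% c(0, 1)) || !all(african_american %in% c(0, 1)))
    stop("indicators must be 0 or 1", call. = FALSE)
  k <- max(length(female), length(african_american), length(year))
  structure(list(female = rep_len(female, k),
                 african_american = rep_len(african_american, k),
                 year = rep_len(year, k)),
            class = "covariate_profile")
}

.check_age <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0))
    stop("'age' must be positive and finite", call. = FALSE)
}

#' Weibull baseline hazard
#'
#' The homogeneous-population (sigma = 0) incidence rate
#' \eqn{\mu_0(x) = (m/c)(x/c)^{m-1}}, the continuous analogue of the
#' Armitage-Doll multistage incidence law.
#'
#' @param age age in years, positive; vectorized.
#' @param params a [frailty_weibull_params()] object (only `m` and `c` used).
#' @return Rate per person-year.
#' @export
weibull_baseline_hazard <- function(age, params) {
  stopifnot(inherits(params, "frailty_weibull_params"))
  .check_age(age)
  (params$m / params$c) * (age / params$c)^(params$m - 1)
}

#' Marginal incidence rate of the frailty-Weibull model
#'
#' Population incidence rate after marginalizing an individual-level
#' proportional frailty `z` (mean 1, variance `sigma^2`, power-variance
#' family indexed by `n`) over survivors:
#' \deqn{\lambda(x) = \frac{m}{c}\left(\frac{x}{c}\right)^{m-1}
#'   \left[1 + n\sigma^2 (x/c)^m\right]^{-1/n},}
#' with the limit \eqn{\lambda(x) = \mu_0(x)\exp(-\sigma^2 (x/c)^m)} as
#' \eqn{n \to 0}. Selection of low-frailty survivors makes the rate fall
#' below the Weibull baseline and, for `m > 1` with positive `sigma`,
#' produces an interior maximum followed by a decline at advanced ages.
#'
#' @inheritParams weibull_baseline_hazard
#' @param params a [frailty_weibull_params()] object.
#' @return Rate per person-year; equals [weibull_baseline_hazard()] when
#'   `sigma = 0`.
#' @export
frailty_marginal_hazard <- function(age, params) {
  stopifnot(inherits(params, "frailty_weibull_params"))
  .check_age(age)
  .hazard_eval(age, params$m, params$c, params$sigma, params$n)
}

# unchecked vectorized evaluation used by the fitting objectives
.hazard_eval <- function(age, m, c, sigma, n) {
  u <- (age / c)^m
  base <- (m / c) * (age / c)^(m - 1)
  s2u <- sigma * sigma * u
  if (n < 1e-12) {
    att <- exp(-s2u)
  } else {
    # (1 + n s2u)^(-1/n) via log1p: stable for small n and large s2u
    att <- exp(-log1p(n * s2u) / n)
  }
  out <- base * att
  if (any(!is.finite(out)))
    stop("hazard evaluation produced non-finite values", call. = FALSE)
  out
}

#' Age at maximal incidence rate
#'
#' Closed-form mode of the marginal hazard:
#' \eqn{x^* = c\,[(m-1)/(\sigma^2 (m - n(m-1)))]^{1/m}}, defined when
#' `m > 1`, `sigma > 0` and `m - n (m - 1) > 0`. Outside that region the
#' hazard is monotone and `NA` is returned.
#'
#' @param params a [frailty_weibull_params()] object.
#' @return Mode age in years, or `NA_real_` when the hazard has no interior
#'   maximum.
#' @export
mode_age <- function(params) {
  stopifnot(inherits(params, "frailty_weibull_params"))
  m <- params$m; n <- params$n; sigma <- params$sigma
  if (m <= 1 || sigma <= 0) return(NA_real_)
  d <- m - n * (m - 1)
  if (d <= 0) return(NA_real_)
  params$c * ((m - 1) / (sigma^2 * d))^(1 / m)
}

#' Covariate multiplier of the generalized model
#'
#' Dimensionless factor
#' \eqn{R_{sex}^{f}\, R_{race}^{b}\, (1 + F_{year}/100)^{(year - ref)/10}}
#' applied to the baseline marginal hazard; equals 1 for the reference
#' profile (male, Caucasian, reference year).
#'
#' @param profile a [covariate_profile()] object.
#' @param cov a [covariate_params()] object.
#' @return Multiplier, vectorized over the profile.
#' @export
covariate_multiplier <- function(profile, cov) {
  stopifnot(inherits(profile, "covariate_profile"),
            inherits(cov, "covariate_params"))
  cov$r_sex^profile$female *
    cov$r_race^profile$african_american *
    (1 + cov$f_year / 100)^((profile$year - cov$ref_year) / 10)
}

#' Generalized (age-year-sex-race) incidence rate
#'
#' The marginal frailty-Weibull hazard multiplied by the covariate factor of
#' [covariate_multiplier()]; reduces to [frailty_marginal_hazard()] for the
#' reference profile.
#'
#' @inheritParams frailty_marginal_hazard
#' @param profile a [covariate_profile()] object.
#' @param cov a [covariate_params()] object.
#' @return Rate per person-year.
#' @export
model2_rate <- function(age, profile, params, cov) {
  frailty_marginal_hazard(age, params) * covariate_multiplier(profile, cov)
}

#' Armitage-Doll multistage hazard
#'
#' The classic homogeneous multistage incidence law \eqn{a\,x^{m-1}}; its
#' log-log slope is `m - 1`. Identical to [weibull_baseline_hazard()] under
#' the reparameterization \eqn{a = m / c^m}.
#'
#' @param age age in years, positive; vectorized.
#' @param a scale parameter (per year^m); `a > 0`.
#' @param m number of stages; `m >= 1`.
#' @return Rate per person-year.
#' @export
armitage_doll_hazard <- function(age, a, m) {
  .check_age(age)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a positive scalar", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1)
    stop("'m' must be a scalar >= 1", call. = FALSE)
  a * age^(m - 1)
}
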