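test_that("baseline hazard matches the closed form and its reductions", {
  expect_equal(weibull_baseline_hazard(50, frailty_weibull_params(2, 50)), 0.04)
  expect_equal(weibull_baseline_hazard(25, frailty_weibull_params(2, 50)), 0.02)
  # m = 1 gives a constant hazard 1/c at every age
  p1 <- frailty_weibull_params(1, 80)
  expect_equal(weibull_baseline_hazard(c(5, 40, 83), p1), rep(0.0125, 3))
  # sigma = 0 marginal hazard is exactly the baseline at every age
  p <- frailty_weibull_params(4.5, 70, 0, 1.2)
  ages <- seq(1, 100, by = 0.5)
  expect_equal(frailty_marginal_hazard(ages, p),
               weibull_baseline_hazard(ages, p))
  # Armitage-Doll identity under a = m / c^m, and log-log slope m - 1
  expect_equal(armitage_doll_hazard(ages, 4.5 / 70^4.5, 4.5),
               weibull_baseline_hazard(ages, p))
  expect_equal(armitage_doll_hazard(10, 1e-10, 5), 1e-6)
  sl <- coef(lm(log(armitage_doll_hazard(20:80, 2e-12, 6)) ~ log(20:80)))[2]
  expect_equal(unname(sl), 5, tolerance = 1e-10)
})

test_that("marginal hazard agrees with numerical frailty-mixture integration", {
  # printed-family cases: gamma (n = 1), inverse Gaussian (n = 2),
  # exponential-attenuation limit (n = 0)
  expect_equal(frailty_marginal_hazard(50, frailty_weibull_params(2, 50, 1, 1)),
               0.02)
  expect_equal(frailty_marginal_hazard(50, frailty_weibull_params(2, 50, 1, 0)),
               0.04 * exp(-1))
  set.seed(421)
  ages <- c(1, 20, 45, 70, 100)
  for (i in 1:10) {
    m <- runif(1, 1.5, 10); c <- runif(1, 50, 120); s <- runif(1, 0.3, 2)
    pg <- frailty_weibull_params(m, c, s, 1)
    pig <- frailty_weibull_params(m, c, s, 2)
    for (x in ages) {
      expect_equal(frailty_marginal_hazard(x, pg),
                   marginal_hazard_oracle(x, m, c, s, "gamma"),
                   tolerance = 1e-6)
      expect_equal(frailty_marginal_hazard(x, pig),
                   marginal_hazard_oracle(x, m, c, s, "ig"),
                   tolerance = 1e-6)
    }
  }
  # spec'd derived case: gamma mixture at (40, m=5, c=80, sigma=2)
  expect_equal(frailty_marginal_hazard(40, frailty_weibull_params(5, 80, 2, 1)),
               marginal_hazard_oracle(40, 5, 80, 2, "gamma"),
               tolerance = 1e-6)
})

test_that("hazard is continuous in n and consistent with its survival", {
  p_lim <- frailty_weibull_params(6, 90, 1.5, 0)
  p_eps <- frailty_weibull_params(6, 90, 1.5, 1e-8)
  ages <- seq(5, 150, by = 5)
  expect_equal(frailty_marginal_hazard(ages, p_eps),
               frailty_marginal_hazard(ages, p_lim), tolerance = 1e-6)
  # for generic n the hazard must equal -d log S/dx of the marginal survival
  # S(x) = exp(-[(1 + n s^2 u)^((n-1)/n) - 1] / (s^2 (n-1))), u = (x/c)^m
  for (n in c(0.5, 1.5)) {
    m <- 5; cc <- 80; s <- 1.2
    logS <- function(x) {
      u <- (x / cc)^m
      -((1 + n * s^2 * u)^((n - 1) / n) - 1) / (s^2 * (n - 1))
    }
    p <- frailty_weibull_params(m, cc, s, n)
    for (x in c(20, 50, 90)) {
      h <- 1e-4 * x
      lam_num <- -(logS(x + h) - logS(x - h)) / (2 * h)
      expect_equal(frailty_marginal_hazard(x, p), lam_num, tolerance = 1e-6)
    }
  }
})

test_that("mode age matches the numerical argmax and encodes monotone cases", {
  expect_equal(mode_age(frailty_weibull_params(2, 50, 1, 1)), 50)
  expect_equal(mode_age(frailty_weibull_params(2, 50, 1, 0)), 50 / sqrt(2))
  expect_true(is.na(mode_age(frailty_weibull_params(2, 50, 0, 1))))
  # no interior maximum when m - n (m - 1) <= 0: hazard keeps rising
  p_mono <- frailty_weibull_params(10, 90, 3, 1.5)  # 10 - 1.5*9 < 0
  expect_true(is.na(mode_age(p_mono)))
  grid <- seq(10, 400, by = 1)
  expect_true(all(diff(frailty_marginal_hazard(grid, p_mono)) > 0))
  set.seed(99)
  for (i in 1:12) {
    m <- runif(1, 1.3, 9); c <- runif(1, 40, 120); s <- runif(1, 0.4, 3)
    n <- runif(1, 0, min(2.5, m / (m - 1) * 0.95))
    p <- frailty_weibull_params(m, c, s, n)
    md <- mode_age(p)
    opt <- optimize(function(x) frailty_marginal_hazard(x, p),
                    c(1e-3, 1000), maximum = TRUE, tol = 1e-8)
    expect_equal(md, opt$maximum, tolerance = 1e-4)
    # strict local maximum and monotone decline beyond the mode
    lam_md <- frailty_marginal_hazard(md, p)
    expect_true(lam_md > frailty_marginal_hazard(md - 1e-3, p))
    expect_true(lam_md > frailty_marginal_hazard(md + 1e-3, p))
    tail <- frailty_marginal_hazard(seq(md * 1.001, md * 5, length.out = 200), p)
    expect_true(all(diff(tail) < 0))
  }
})

test_that("covariate multiplier and the generalized rate satisfy the identities", {
  cov <- covariate_params(r_sex = 0.25, r_race = 1.33, f_year = -6.86,
                          ref_year = 1988)
  ref <- covariate_profile(0, 0, 1988)
  expect_equal(covariate_multiplier(ref, cov), 1.0)
  expect_equal(covariate_multiplier(covariate_profile(1, 0, 1988), cov), 0.25)
  # a +33.20% decadal trend raises rates by x1.332 ten years past the anchor
  cov_ac <- covariate_params(f_year = 33.20, ref_year = 1988)
  expect_equal(covariate_multiplier(covariate_profile(0, 0, 1998), cov_ac),
               1.332)
  p <- lung_ac_params()
  ages <- 30:84 + 0.5
  expect_equal(model2_rate(ages, ref, p, cov),
               frailty_marginal_hazard(ages, p))
  # r_sex x r_race = 1 restores the baseline rate
  cov2 <- covariate_params(r_sex = 0.5, r_race = 2.0)
  expect_equal(model2_rate(ages, covariate_profile(1, 1, 1988), p, cov2),
               frailty_marginal_hazard(ages, p))
  # rate ratio between two years 10 apart is 1 + f_year/100 for any profile
  r1 <- model2_rate(ages, covariate_profile(1, 1, 1995), p, cov)
  r0 <- model2_rate(ages, covariate_profile(1, 1, 1985), p, cov)
  expect_equal(r1 / r0, rep(1 - 0.0686, length(ages)))
})

test_that("hazard functions reject invalid inputs", {
  p <- lung_ac_params()
  expect_error(weibull_baseline_hazard(-1, p), "positive")
  expect_error(frailty_marginal_hazard(0, p), "positive")
  expect_error(frailty_weibull_params(0.5, 50), "m")
  expect_error(frailty_weibull_params(2, -3), "c")
  expect_error(frailty_weibull_params(2, 50, -1), "sigma")
  expect_error(covariate_params(r_sex = 0), "positive")
  expect_error(covariate_params(f_year = -120), "f_year")
  expect_error(covariate_profile(female = 2), "0 or 1")
  expect_error(armitage_doll_hazard(10, -1, 5), "'a'")
})
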