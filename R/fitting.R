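#' Fitting configuration
#'
#' Controls the estimation machinery shared by [fit_model1()],
#' [fit_model2()], [fit_apc()] and [compare_models()]. The weighted
#' nonlinear least-squares objective is multimodal in (`sigma`, `n`), so the
#' optimizer (bounded quasi-Newton, L-BFGS-B) is restarted from a
#' data-driven initial point plus Latin-hypercube draws within the bounds;
#' the best run by objective (ties broken by the smaller `m`) is kept and
#' re-polished once.
#'
#' @param method `"wnls"` (weighted nonlinear least squares with
#'   Wilson-variance weights) or `"mle"` (Poisson maximum likelihood).
#' @param multistart number of optimizer starts (>= 1).
#' @param seed integer seed controlling the multistart draws; identical
#'   configuration and seed give bit-identical fits.
#' @param bounds named list of `c(lower, upper)` overriding the defaults
#'   (`m` in \[1, 30\], `c` in \[10, 250\] years, `sigma` in \[0, 400\],
#'   `n` in \[0, 3\], relative risks in \[0.01, 10\], `f_year` in
#'   \[-90, 400\] percent).
#' @param fix named numeric vector of parameters held fixed at the given
#'   values (e.g. `c(sigma = 0)` for the Weibull submodel).
#' @param max_iter optimizer iteration cap per start.
#' @param z Wilson score quantile used for the weights.
#' @param reweight number of reweighting passes for `method = "wnls"`: after
#'   the multistart optimization the Wilson variances are recomputed from
#'   the *expected* counts `person_years x fitted rate` and the fit is
#'   re-polished. Weights built from observed counts are correlated with the
#'   sampling errors of the rates (cells with randomly low counts get
#'   randomly high weight), which biases the shape parameter upward in
#'   low-count panels; one expected-count pass removes this while keeping
#'   the Wilson variance form. Set to 0 for pure observed-count weights.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(method = c("wnls", "mle"), multistart = 8L, seed = 1L,
                       bounds = list(), fix = NULL, max_iter = 500L,
                       z = 1.96, reweight = 1L) {
  method <- match.arg(method)
  if (multistart < 1) stop("'multistart' must be >= 1", call. = FALSE)
  if (!is.null(fix) && is.null(names(fix)))
    stop("'fix' must be a named numeric vector", call. = FALSE)
  structure(list(method = method, multistart = as.integer(multistart),
                 seed = as.integer(seed), bounds = bounds, fix = fix,
                 max_iter = as.integer(max_iter), z = z,
                 reweight = as.integer(reweight)),
            class = "fit_config")
}

.default_bounds <- function() {
  list(m = c(1, 30), c = c(10, 250), sigma = c(0, 400), n = c(0, 3),
       r_sex = c(0.01, 10), r_race = c(0.01, 10), f_year = c(-90, 400),
       log_a = c(-60, 5), q = c(-5, 5))
}

.bounds_for <- function(names, config) {
  b <- .default_bounds()
  for (nm in names(config$bounds)) b[[nm]] <- config$bounds[[nm]]
  for (nm in names) {
    if (is.null(b[[nm]])) b[[nm]] <- c(-5, 5)  # log-scale APC multipliers
    if (b[[nm]][1] >= b[[nm]][2])
      stop("invalid bounds for '", nm, "'", call. = FALSE)
  }
  lo <- vapply(names, function(nm) b[[nm]][1], numeric(1))
  hi <- vapply(names, function(nm) b[[nm]][2], numeric(1))
  list(lower = lo, upper = hi)
}

# prepare a fitting frame: midpoints, rates, Wilson weights
.fit_frame <- function(table, z) {
  stopifnot(inherits(table, "incidence_table"))
  df <- as.data.frame(table)
  rv <- rate_and_variance(df$count, df$person_years, z)
  df$x <- df$age + attr(table, "bin_width") / 2
  df$rate <- rv$rate
  df$variance <- rv$variance
  df$w <- 1 / rv$variance
  df
}

# pooled single-pattern frame: collapse strata to one row per age
.collapse_by_age <- function(table, z) {
  df <- as.data.frame(table)
  agg <- stats::aggregate(cbind(count, person_years) ~ age, data = df, FUN = sum)
  tab <- incidence_table(
    data.frame(age = agg$age, year = stats::median(df$year),
               female = 0L, african_american = 0L,
               count = agg$count, person_years = agg$person_years),
    cancer_label = attr(table, "cancer_label"),
    histotype = attr(table, "histotype"),
    min_age = attr(table, "min_age"),
    bin_width = attr(table, "bin_width"))
  .fit_frame(tab, z)
}

# rate closures -------------------------------------------------------------

.rate_fn_single <- function(kind, x) {
  switch(kind,
    armitage_doll = function(th) exp(th[["log_a"]]) * x^(th[["m"]] - 1),
    weibull = function(th)
      (th[["m"]] / th[["c"]]) * (x / th[["c"]])^(th[["m"]] - 1),
    frailty_weibull = function(th)
      .hazard_try(x, th[["m"]], th[["c"]], th[["sigma"]], th[["n"]]),
    stop("unknown model kind: ", kind, call. = FALSE))
}

.rate_fn_model2 <- function(df, ref_year, quadratic = FALSE) {
  # factorized evaluation: the hazard depends only on the (few) unique ages
  # and the trend factor only on the unique years, so transcendental calls
  # shrink by ~the panel depth; arithmetic is identical to the cell-wise form
  ux <- unique(df$x); ix <- match(df$x, ux)
  uy <- unique(df$year); iy <- match(df$year, uy)
  dyu <- (uy - ref_year) / 10
  fem1 <- df$female + 1L; aa1 <- df$african_american + 1L
  function(th) {
    lam <- .hazard_try(ux, th[["m"]], th[["c"]], th[["sigma"]], th[["n"]])[ix]
    tru <- (1 + th[["f_year"]] / 100)^dyu
    if (quadratic) tru <- tru * exp(th[["q"]] * dyu^2)
    mult <- c(1, th[["r_sex"]])[fem1] * c(1, th[["r_race"]])[aa1] * tru[iy]
    lam * mult
  }
}

.hazard_try <- function(x, m, c, sigma, n) {
  if (c <= 0 || m < 1 || n < 0) return(rep(NaN, length(x)))
  u <- (x / c)^m
  base <- (m / c) * (x / c)^(m - 1)
  s2u <- sigma * sigma * u
  if (n < 1e-12) base * exp(-s2u) else base * exp(-log1p(n * s2u) / n)
}

# objectives -----------------------------------------------------------------

.objective <- function(method, rate_fn, df) {
  if (method == "wnls") {
    obs <- df$rate; w <- df$w
    function(th) {
      r <- rate_fn(th)
      if (any(!is.finite(r)) || any(r < 0)) return(1e30)
      sum(w * (obs - r)^2)
    }
  } else {
    k <- df$count; py <- df$person_years
    function(th) {
      r <- rate_fn(th)
      if (any(!is.finite(r)) || any(r < 0)) return(1e30)
      mu <- pmax(py * r, 1e-12)
      val <- sum(mu - k * log(mu))
      if (!is.finite(val)) 1e30 else val
    }
  }
}

# multistart bounded quasi-Newton over the free parameters
.fit_core <- function(df, rate_fn, par_names, init, config, model,
                      notes = character()) {
  fixed <- config$fix
  fixed <- fixed[names(fixed) %in% par_names]
  free <- setdiff(par_names, names(fixed))
  if (length(free) == 0L) stop("no free parameters", call. = FALSE)
  n_pts <- nrow(df)
  if (n_pts <= length(free))
    stop("fewer data points than free parameters", call. = FALSE)
  if (all(df$count == 0))
    stop("degenerate data: all counts are zero", call. = FALSE)

  bb <- .bounds_for(free, config)
  full0 <- init
  full0[names(fixed)] <- fixed
  clamp <- function(v) pmin(pmax(v, bb$lower), bb$upper)
  start0 <- clamp(full0[free])

  assemble <- function(th_free) {
    full <- full0
    full[free] <- th_free
    full
  }
  make_obj <- function(frame) {
    f <- .objective(config$method, rate_fn, frame)
    function(th_free) f(assemble(th_free))
  }
  obj_free <- make_obj(df)

  set.seed(config$seed)
  k <- config$multistart
  starts <- matrix(rep(start0, each = k), nrow = k,
                   dimnames = list(NULL, free))
  if (k >= 2) {
    jit <- clamp(start0 * stats::runif(length(free), 0.7, 1.3) +
                   stats::runif(length(free), -0.05, 0.05))
    starts[2, ] <- jit
  }
  if (k >= 3) {
    u <- lhs::randomLHS(k - 2, length(free))
    for (j in seq_along(free))
      starts[3:k, j] <- bb$lower[j] + u[, j] * (bb$upper[j] - bb$lower[j])
  }

  parscale <- pmax((bb$upper - bb$lower) / 10, 1e-3)
  run_one <- function(p0, fn = obj_free, factr = 1e7, ndeps = 1e-3,
                      maxit = config$max_iter) {
    tryCatch(
      stats::optim(p0, fn, method = "L-BFGS-B",
                   lower = bb$lower, upper = bb$upper,
                   control = list(maxit = maxit,
                                  parscale = parscale, factr = factr,
                                  ndeps = rep(ndeps, length(p0)))),
      error = function(e) list(par = p0, value = Inf, convergence = 99L))
  }
  fits <- lapply(seq_len(k), function(i) run_one(starts[i, ]))
  vals <- vapply(fits, function(f) f$value, numeric(1))
  ms <- vapply(fits, function(f)
    if ("m" %in% free) f$par[["m"]] else full0[["m"]], numeric(1))
  best <- order(vals, ms)[1]
  opt <- fits[[best]]
  # tight polish rounds from the best run, with finer gradient steps;
  # stop once the objective is stationary
  last_code <- opt$convergence
  rel_change <- Inf
  for (round in 1:3) {
    nxt <- run_one(opt$par, factr = 1e2, ndeps = 1e-6, maxit = 300L)
    rel_change <- abs(opt$value - nxt$value) / (abs(opt$value) + 1e-300)
    last_code <- nxt$convergence
    if (is.finite(nxt$value) && nxt$value <= opt$value) opt <- nxt
    if (last_code == 0L || rel_change < 1e-8) break
  }
  converged <- is.finite(opt$value) && opt$value < 1e29 &&
    (last_code == 0L || rel_change < 1e-6)
  if (!converged)
    notes <- c(notes, "optimizer did not converge from any start")

  est_free <- opt$par
  names(est_free) <- free
  estimates <- assemble(est_free)
  fitted_rate <- rate_fn(estimates)

  # expected-count reweighting passes (see fit_config)
  if (config$method == "wnls" && config$reweight > 0 && converged) {
    for (it in seq_len(config$reweight)) {
      mu <- pmax(fitted_rate, 0) * df$person_years
      df$w <- 1 / rate_and_variance(mu, df$person_years, config$z)$variance
      obj_free <- make_obj(df)
      opt2 <- run_one(est_free, obj_free, factr = 1e2, ndeps = 1e-6,
                      maxit = 300L)
      if (is.finite(opt2$value)) {
        est_free <- opt2$par
        names(est_free) <- free
        estimates <- assemble(est_free)
        fitted_rate <- rate_fn(estimates)
      }
    }
  }

  # goodness of fit always on the Wilson-weighted scale
  wss <- sum(df$w * (df$rate - fitted_rate)^2)
  dof <- n_pts - length(free)
  chi2_dof <- wss / dof

  vcov <- .fit_vcov(config, obj_free, rate_fn, assemble, est_free, df,
                    chi2_dof, bb)
  se <- rep(0, length(estimates))
  names(se) <- names(estimates)
  se[free] <- sqrt(pmax(diag(vcov), 0))

  fit <- structure(list(
    model = model, method = config$method,
    estimates = estimates, se = se, vcov = vcov,
    free = free, fixed = fixed,
    objective = opt$value, chi2_dof = chi2_dof,
    converged = converged, n_points = n_pts, n_free = length(free),
    data = df, fitted = fitted_rate, notes = notes,
    config = config), class = "mstage_fit")
  fit$diagnostics <- residual_diagnostics(fit)
  fit
}

# curvature-based covariance: Jacobian (WNLS) or observed information (MLE)
.fit_vcov <- function(config, obj_free, rate_fn, assemble, est_free, df,
                      chi2_dof, bb) {
  p <- length(est_free)
  if (config$method == "wnls") {
    J <- matrix(0, nrow(df), p)
    h <- pmax(1e-5 * pmax(abs(est_free), 1), 1e-7)
    for (j in seq_len(p)) {
      # one-sided steps at active bounds (e.g. sigma or n at 0)
      up <- est_free; up[j] <- min(up[j] + h[j], bb$upper[j])
      dn <- est_free; dn[j] <- max(dn[j] - h[j], bb$lower[j])
      J[, j] <- (rate_fn(assemble(up)) - rate_fn(assemble(dn))) /
        (up[j] - dn[j])
    }
    A <- crossprod(J * sqrt(df$w))
    V <- .safe_solve(A) * chi2_dof
  } else {
    H <- tryCatch(
      stats::optimHess(est_free, obj_free,
                       control = list(parscale = pmax(abs(est_free), 1e-2))),
      error = function(e) NULL)
    V <- if (is.null(H)) matrix(NA_real_, p, p) else .safe_solve(H)
  }
  dimnames(V) <- list(names(est_free), names(est_free))
  V
}

.safe_solve <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(A)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# initial values -------------------------------------------------------------

.init_baseline <- function(x, rate, bounds_m = c(1, 30), bounds_c = c(10, 250)) {
  pos <- rate > 0
  if (sum(pos) < 3) return(c(m = 5, c = 90, sigma = 1, n = 1))
  imax <- which.max(rate)
  rising <- pos & seq_along(x) <= max(imax, 4)
  if (sum(rising) < 3) rising <- pos
  sl <- tryCatch(stats::coef(stats::lm(log(rate[rising]) ~ log(x[rising])))[2],
                 error = function(e) 5)
  m0 <- min(max(sl + 1, bounds_m[1] + 0.5), bounds_m[2] - 0.5)
  c0 <- if (imax < length(x)) x[imax] else max(x) * 1.2
  c0 <- min(max(c0, bounds_c[1] + 1), bounds_c[2] - 1)
  c(m = unname(m0), c = unname(c0), sigma = 1, n = 1)
}

.init_covariates <- function(df) {
  wm <- function(r, py) if (length(r)) sum(r * py) / sum(py) else NA_real_
  ratio <- function(flag) {
    a <- wm(df$rate[flag == 1], df$person_years[flag == 1])
    b <- wm(df$rate[flag == 0], df$person_years[flag == 0])
    if (is.na(a) || is.na(b) || b <= 0 || a <= 0) 1 else min(max(a / b, 0.02), 9)
  }
  yr <- sort(unique(df$year))
  f0 <- 0
  if (length(yr) >= 3) {
    tot <- vapply(yr, function(y)
      wm(df$rate[df$year == y], df$person_years[df$year == y]), numeric(1))
    ok <- tot > 0
    if (sum(ok) >= 3) {
      b <- tryCatch(stats::coef(stats::lm(log(tot[ok]) ~ yr[ok]))[2],
                    error = function(e) 0)
      f0 <- min(max(100 * (exp(10 * b) - 1), -80), 300)
    }
  }
  c(r_sex = ratio(df$female), r_race = ratio(df$african_american),
    f_year = unname(f0))
}

# fit operations -------------------------------------------------------------

#' Fit the frailty-Weibull model to a single age pattern
#'
#' Pools all strata of the table by age (summing counts and person-years) and
#' estimates (`m`, `c`, `sigma`, `n`) from the age-specific rates, weighting
#' by the reciprocal Wilson variance ([rate_and_variance()]) for
#' `method = "wnls"`, or maximizing the Poisson likelihood of the counts for
#' `method = "mle"`. Standard errors come from the curvature of the
#' objective at the optimum (Jacobian-based, scaled by the residual
#' chi-square per degree of freedom, for WNLS; observed information for
#' MLE).
#'
#' @param table an [incidence_table()] (already age-filtered, see
#'   [filter_min_age()]).
#' @param config a [fit_config()].
#' @param start optional named numeric vector of initial values overriding
#'   the data-driven heuristic (`m` from the log-log slope of the rising
#'   limb + 1, `c` from the age of the empirical maximum, `sigma = 1`,
#'   `n = 1`).
#' @return An object of class `mstage_fit`.
#' @export
fit_model1 <- function(table, config = fit_config(), start = NULL) {
  df <- .collapse_by_age(table, config$z)
  if (nrow(df) < 10)
    stop("need at least 10 age points", call. = FALSE)
  init <- .init_baseline(df$x, df$rate)
  if (!is.null(start)) init[names(start)] <- start
  rate_fn <- .rate_fn_single("frailty_weibull", df$x)
  .fit_core(df, rate_fn, c("m", "c", "sigma", "n"), init, config,
            model = "frailty_weibull")
}

#' Fit the covariate-generalized model to a full panel
#'
#' Joint weighted fit of the baseline parameters and the covariate factors
#' (`r_sex`, `r_race`, `f_year`) over all age x year x sex x race cells.
#' Covariates that are constant in the panel are automatically held at their
#' reference value (relative risks at 1, the period trend at 0) and flagged
#' as unidentifiable in the fit notes.
#'
#' @inheritParams fit_model1
#' @param ref_year calendar year anchoring the period-trend factor.
#' @param quadratic also estimate a quadratic period term `q`, multiplying
#'   the rate by `exp(q ((year - ref_year)/10)^2)` (sensitivity analysis).
#' @return An object of class `mstage_fit` whose `estimates` include the
#'   covariate parameters.
#' @export
fit_model2 <- function(table, config = fit_config(), ref_year = 1988L,
                       quadratic = FALSE, start = NULL) {
  df <- .fit_frame(table, config$z)
  notes <- character()
  fix <- config$fix
  if (length(unique(df$female)) < 2 && !("r_sex" %in% names(fix))) {
    fix <- c(fix, r_sex = 1)
    notes <- c(notes, "r_sex unidentifiable (single-sex panel); fixed at 1")
    warning("single-sex panel: r_sex fixed at 1", call. = FALSE)
  }
  if (length(unique(df$african_american)) < 2 && !("r_race" %in% names(fix))) {
    fix <- c(fix, r_race = 1)
    notes <- c(notes, "r_race unidentifiable (single-race panel); fixed at 1")
    warning("single-race panel: r_race fixed at 1", call. = FALSE)
  }
  if (length(unique(df$year)) < 2 && !("f_year" %in% names(fix))) {
    fix <- c(fix, f_year = 0)
    notes <- c(notes, "f_year unidentifiable (single-year panel); fixed at 0")
  }
  config$fix <- fix
  pooled <- .collapse_by_age(table, config$z)
  init <- c(.init_baseline(pooled$x, pooled$rate), .init_covariates(df))
  par_names <- c("m", "c", "sigma", "n", "r_sex", "r_race", "f_year")
  if (quadratic) {
    init <- c(init, q = 0)
    par_names <- c(par_names, "q")
  }
  if (!is.null(start)) init[names(start)] <- start
  rate_fn <- .rate_fn_model2(df, ref_year, quadratic)
  fit <- .fit_core(df, rate_fn, par_names, init, config,
                   model = "model2", notes = notes)
  fit$ref_year <- as.integer(ref_year)
  fit
}

#' Goodness of fit per degree of freedom
#'
#' Weighted residual sum of squares over `n - p` degrees of freedom, the
#' statistic used to judge whether a fitted age pattern is consistent with
#' sampling noise (values near 1).
#'
#' @param fit an `mstage_fit`.
#' @param table optional [incidence_table()] to evaluate against (defaults
#'   to the fitting data).
#' @return chi-square per degree of freedom.
#' @export
goodness_of_fit <- function(fit, table = NULL) {
  stopifnot(inherits(fit, "mstage_fit"))
  if (is.null(table)) {
    df <- fit$data
    fitted <- fit$fitted
  } else {
    df <- .fit_frame(table, fit$config$z)
    if (nrow(df) != length(fit$fitted))
      stop("table does not match the fitted data layout", call. = FALSE)
    fitted <- fit$fitted
  }
  dof <- nrow(df) - fit$n_free
  if (dof <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  sum(df$w * (df$rate - fitted)^2) / dof
}

#' Residual diagnostics of a fit
#'
#' Weighted residuals are screened for normality (moment-based omnibus test
#' on skewness and excess kurtosis), heteroscedasticity (rank correlation of
#' squared residuals with fitted values) and autocorrelation (Durbin-Watson
#' statistic over age ordering within strata). With fewer than 20 residuals,
#' or residuals that are numerically zero, the diagnostics are marked
#' unavailable.
#'
#' @param fit an `mstage_fit`.
#' @return A list of class `residual_diagnostics` with elements `available`,
#'   `normality_p`, `heteroscedasticity_p`, `autocorrelation_stat`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mstage_fit"))
  df <- fit$data
  ord <- order(df$female, df$african_american, df$year, df$age)
  r <- (df$rate - fit$fitted)[ord] * sqrt(df$w[ord])
  out <- list(available = FALSE, normality_p = NA_real_,
              heteroscedasticity_p = NA_real_,
              autocorrelation_stat = NA_real_)
  class(out) <- "residual_diagnostics"
  scale <- stats::sd(df$rate[ord] * sqrt(df$w[ord]))
  if (length(r) < 20 || stats::sd(r) < 1e-6 * (scale + 1e-300)) return(out)
  n <- length(r)
  z <- r - mean(r)
  s <- sqrt(mean(z^2))
  skew <- mean(z^3) / s^3
  kurt <- mean(z^4) / s^4
  jb <- n * (skew^2 / 6 + (kurt - 3)^2 / 24)
  out$normality_p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  het <- suppressWarnings(
    stats::cor.test(r^2, fit$fitted[ord], method = "spearman", exact = FALSE))
  out$heteroscedasticity_p <- het$p.value
  out$autocorrelation_stat <- sum(diff(r)^2) / sum(r^2)
  out$available <- TRUE
  out
}

#' Compare candidate carcinogenesis models on one age pattern
#'
#' Fits each candidate to the pooled age pattern, ranks converged fits by
#' chi-square per degree of freedom, and reports F-tests for the nested
#' pairs (the homogeneous Armitage-Doll/Weibull laws are 2-parameter
#' submodels of the 4-parameter frailty-Weibull model; Armitage-Doll and
#' Weibull are reparameterizations of the same law and are not tested
#' against each other).
#'
#' @param table an [incidence_table()].
#' @param candidates subset of
#'   `c("armitage_doll", "weibull", "frailty_weibull")`.
#' @param config a [fit_config()].
#' @return list with elements `ranking` (data.frame ordered by `chi2_dof`),
#'   `tests` (data.frame of nested F-tests) and `fits` (named list).
#' @export
compare_models <- function(table,
                           candidates = c("armitage_doll", "weibull",
                                          "frailty_weibull"),
                           config = fit_config()) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  df <- .collapse_by_age(table, config$z)
  fits <- list()
  for (kind in candidates) {
    par_names <- switch(kind,
      armitage_doll = c("log_a", "m"),
      weibull = c("m", "c"),
      frailty_weibull = c("m", "c", "sigma", "n"))
    init <- .init_baseline(df$x, df$rate)
    if (kind == "armitage_doll") {
      init <- c(log_a = unname(log(init[["m"]]) - init[["m"]] * log(init[["c"]])),
                m = init[["m"]])
    } else {
      init <- init[par_names]
    }
    cfg <- config
    cfg$fix <- config$fix[names(config$fix) %in% par_names]
    f <- tryCatch(
      .fit_core(df, .rate_fn_single(kind, df$x), par_names, init, cfg,
                model = kind),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      warning("candidate '", kind, "' did not converge; excluded",
              call. = FALSE)
      next
    }
    fits[[kind]] <- f
  }
  if (length(fits) == 0L) stop("no candidate converged", call. = FALSE)
  ranking <- data.frame(
    model = names(fits),
    n_free = vapply(fits, function(f) f$n_free, integer(1)),
    objective = vapply(fits, function(f) f$objective, numeric(1)),
    chi2_dof = vapply(fits, function(f) f$chi2_dof, numeric(1)),
    row.names = NULL)
  ranking <- ranking[order(ranking$chi2_dof), ]
  tests <- NULL
  if ("frailty_weibull" %in% names(fits)) {
    full <- fits[["frailty_weibull"]]
    n <- full$n_points
    for (nul in intersect(c("armitage_doll", "weibull"), names(fits))) {
      r0 <- .wss(fits[[nul]]); r1 <- .wss(full)
      dp <- full$n_free - fits[[nul]]$n_free
      dn <- n - full$n_free
      fstat <- max(((r0 - r1) / dp) / (r1 / dn), 0)
      tests <- rbind(tests, data.frame(
        null_model = nul, full_model = "frailty_weibull",
        f_statistic = fstat, df1 = dp, df2 = dn,
        p_value = stats::pf(fstat, dp, dn, lower.tail = FALSE)))
    }
  }
  list(ranking = ranking, tests = tests, fits = fits)
}

.wss <- function(fit) sum(fit$data$w * (fit$data$rate - fit$fitted)^2)

#' @export
print.mstage_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s), %d points, chi2/dof = %.3g, converged: %s\n",
              x$model, x$method, x$n_points, x$chi2_dof, x$converged))
  est <- rbind(estimate = x$estimates, se = x$se)
  print(round(est, 4))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Fitted-curve table of a fit
#'
#' @param fit an `mstage_fit`.
#' @return data.frame with age, stratum, observed and fitted rates, and the
#'   weighted residual.
#' @export
fitted_curve <- function(fit) {
  stopifnot(inherits(fit, "mstage_fit"))
  df <- fit$data
  data.frame(age = df$age, year = df$year, female = df$female,
             african_american = df$african_american,
             observed = df$rate, fitted = fit$fitted,
             residual = (df$rate - fit$fitted) * sqrt(df$w))
}

#' Serialize a fit to a JSON-ready report
#'
#' @param fit an `mstage_fit`.
#' @return A nested list (estimates, standard errors, fit statistics,
#'   diagnostics, convergence metadata) suitable for
#'   [jsonlite::write_json()].
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "mstage_fit"))
  d <- fit$diagnostics
  list(model = fit$model, method = fit$method,
       estimates = as.list(fit$estimates), se = as.list(fit$se),
       chi2_dof = fit$chi2_dof, objective = fit$objective,
       converged = fit$converged, n_points = fit$n_points,
       n_free = fit$n_free, notes = fit$notes,
       diagnostics = list(available = d$available,
                          normality_p = d$normality_p,
                          heteroscedasticity_p = d$heteroscedasticity_p,
                          autocorrelation_stat = d$autocorrelation_stat),
       seed = fit$config$seed)
}
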