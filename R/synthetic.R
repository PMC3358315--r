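#' Specification of a synthetic registry cohort
#'
#' Defines the generating process of a SEER-like incidence panel: the
#' frailty-Weibull baseline, the covariate factors, an optional APC
#' structure, the age and calendar-year ranges, the strata to include and
#' the exposure model. Counts are later drawn Poisson around
#' `person_years x rate` by [simulate_panel()]; at registry rates (well
#' below one per person-year) the Poisson and binomial sampling models are
#' indistinguishable and Poisson matches the likelihood used by
#' `method = "mle"` fits.
#'
#' @param params a [frailty_weibull_params()].
#' @param cov a [covariate_params()]; when `apc` is supplied its `f_year`
#'   must be 0 (the APC substitution replaces the parametric trend).
#' @param apc optional [apc_params()].
#' @param ages integer vector of 1-year age-bin starts.
#' @param years integer vector of calendar years.
#' @param strata data.frame with columns `female`, `african_american`
#'   giving the population groups (default: both sexes x both races).
#' @param exposure person-years per cell: a positive scalar or a function
#'   `f(age, female, african_american)` (e.g. to taper exposure above age
#'   80 and mimic registry thinning).
#' @param seed integer seed making the draw reproducible.
#' @param cancer_label,histotype,min_age metadata passed to
#'   [incidence_table()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(params, cov = covariate_params(), apc = NULL,
                        ages = 30:84, years = 1973:2003,
                        strata = data.frame(
                          female = c(0, 1, 0, 1),
                          african_american = c(0, 0, 1, 1)),
                        exposure = 2e5, seed = 1L,
                        cancer_label = "synthetic",
                        histotype = c("other", "AC", "SCC"),
                        min_age = min(ages)) {
  stopifnot(inherits(params, "frailty_weibull_params"),
            inherits(cov, "covariate_params"))
  histotype <- match.arg(histotype)
  if (length(ages) == 0L || length(years) == 0L)
    stop("age and year ranges must be non-empty", call. = FALSE)
  if (!is.null(apc)) {
    stopifnot(inherits(apc, "apc_params"))
    if (cov$f_year != 0)
      stop("with an APC structure, 'f_year' must be 0", call. = FALSE)
  }
  if (is.numeric(exposure)) {
    if (any(exposure <= 0)) stop("exposure must be positive", call. = FALSE)
    e <- exposure
    exposure <- function(age, female, african_american) rep(e, length(age))
  }
  structure(list(params = params, cov = cov, apc = apc,
                 ages = as.integer(ages), years = as.integer(years),
                 strata = strata, exposure = exposure, seed = as.integer(seed),
                 cancer_label = cancer_label, histotype = histotype,
                 min_age = as.integer(min_age)),
            class = "cohort_spec")
}

#' Simulate a registry-like incidence panel
#'
#' Draws a Poisson count for every (age, year, stratum) cell with mean
#' `person_years x rate`, where the rate is [model2_rate()] (or [apc_rate()]
#' when the spec carries an APC structure) evaluated at the age-bin midpoint.
#' Identical seeds give identical panels.
#'
#' @param spec a [cohort_spec()].
#' @return An [incidence_table()].
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- expand.grid(age = spec$ages, year = spec$years,
                      stratum = seq_len(nrow(spec$strata)))
  grid$female <- spec$strata$female[grid$stratum]
  grid$african_american <- spec$strata$african_american[grid$stratum]
  x <- grid$age + 0.5
  prof <- covariate_profile(grid$female, grid$african_american, grid$year)
  rate <- if (is.null(spec$apc)) {
    model2_rate(x, prof, spec$params, spec$cov)
  } else {
    apc_rate(x, prof, spec$params, spec$cov, spec$apc)
  }
  py <- spec$exposure(grid$age, grid$female, grid$african_american)
  mu <- py * rate
  if (any(mu > 1e9))
    stop("expected counts exceed 1e9; rescale the exposure model",
         call. = FALSE)
  set.seed(spec$seed)
  counts <- stats::rpois(length(mu), mu)
  incidence_table(
    data.frame(age = grid$age, year = grid$year, female = grid$female,
               african_american = grid$african_american, count = counts,
               person_years = py),
    cancer_label = spec$cancer_label, histotype = spec$histotype,
    min_age = spec$min_age)
}

#' Simulate a drifting stage-at-diagnosis series
#'
#' Produces one stage distribution per year by applying per-category linear
#' drifts (percentage points per year) to a base distribution, optionally
#' perturbed by Gaussian noise, then clipping to \[0, 100\] and renormalizing
#' so every year keeps the base total.
#'
#' @param base a single-row [stage_distribution()].
#' @param drift named numeric vector of drifts for a subset of
#'   `c("in_situ", "localized", "regional", "distant", "unstaged")`,
#'   in percentage points per year.
#' @param years integer years to generate.
#' @param seed integer seed (only consumed when `noise_sd > 0`).
#' @param noise_sd standard deviation of pre-normalization Gaussian noise.
#' @return A [stage_distribution()] with one row per year.
#' @export
simulate_stage_table <- function(base, drift = numeric(), years,
                                 seed = 1L, noise_sd = 0) {
  base <- stage_distribution(base)
  if (nrow(base) != 1L) stop("'base' must be a single row", call. = FALSE)
  cats <- c(.stage_cats, "unstaged")
  d <- stats::setNames(numeric(length(cats)), cats)
  d[names(drift)] <- drift
  total <- sum(as.numeric(base[cats]))
  set.seed(seed)
  rows <- lapply(seq_along(years), function(i) {
    fr <- as.numeric(base[cats]) + d * (years[i] - years[1])
    if (noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
    fr <- pmin(pmax(fr, 0), 100)
    if (sum(fr) > 0) fr <- fr * total / sum(fr)
    out <- data.frame(cancer = base$cancer, year = years[i])
    out[cats] <- as.list(fr)
    out
  })
  stage_distribution(do.call(rbind, rows))
}

#' Fitted parameters of the 26 studied cancer sites
#'
#' Returns the versioned fixture of per-cancer model parameters (age scale,
#' m-stages, frailty shape and standard deviation, sex/race relative risks,
#' period trend, minimum analysis age, fit quality) for the 14
#' adenocarcinomas and 12 squamous cell carcinomas, used as generating
#' values for the synthetic panel library.
#'
#' @return data.frame, one row per cancer.
#' @export
seer_cancer_parameters <- function() {
  utils::read.csv(system.file("extdata", "seer_cancer_parameters.csv",
                              package = "mstagefrailty", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Build a cohort spec from a parameter-table row
#'
#' @param row single-row data.frame in the layout of [seer_cancer_parameters()].
#' @param ages age-bin starts; defaults to `row$age_min:84`.
#' @param years calendar years of the panel.
#' @param strata,exposure,seed passed to [cohort_spec()].
#' @param ref_year anchor of the period trend.
#' @return A [cohort_spec()].
#' @export
spec_from_parameters <- function(row, ages = NULL, years = 1973:2003,
                                 strata = data.frame(
                                   female = c(0, 1, 0, 1),
                                   african_american = c(0, 0, 1, 1)),
                                 exposure = 2e5, seed = 1L,
                                 ref_year = 1988L) {
  if (is.null(ages)) ages <- row$age_min:84
  cohort_spec(
    params = frailty_weibull_params(m = row$m, c = row$c,
                                    sigma = row$sigma, n = row$n),
    cov = covariate_params(r_sex = row$r_sex, r_race = row$r_race,
                           f_year = row$f_year, ref_year = ref_year),
    ages = ages, years = years, strata = strata, exposure = exposure,
    seed = seed, cancer_label = row$cancer, histotype = row$histotype,
    min_age = row$age_min)
}

#' Synthetic panel library over all 26 cancers
#'
#' One [cohort_spec()] per parameter row: 14 adenocarcinoma and 12 squamous
#' cell carcinoma generators whose parameter values equal the bundled
#' per-cancer estimates to printed precision.
#'
#' @inheritParams spec_from_parameters
#' @param seed base seed; spec `i` uses `seed + i`.
#' @return Named list of class `panel_library`.
#' @export
build_panel_library <- function(years = 1973:2003,
                                 strata = data.frame(
                                   female = c(0, 1, 0, 1),
                                   african_american = c(0, 0, 1, 1)),
                                 exposure = 2e5, seed = 1L) {
  tab <- seer_cancer_parameters()
  specs <- lapply(seq_len(nrow(tab)), function(i)
    spec_from_parameters(tab[i, ], years = years, strata = strata,
                         exposure = exposure, seed = seed + i))
  names(specs) <- tab$cancer
  structure(specs, class = "panel_library")
}
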