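#' Binned age-period-cohort multipliers
#'
#' Nonparametric cohort and period effects attached to the carcinogenesis
#' model: the parametric period trend `f_year` is replaced by positive
#' multipliers on birth-cohort bins (10-year by default) and calendar-period
#' bins (5-year by default). The multipliers at the reference bins are fixed
#' to exactly 1; this normalization removes the rescaling indeterminacy
#' (multiplying all cohort effects by k and all period effects by 1/k leaves
#' rates unchanged).
#'
#' @param g_cohort named positive numeric vector of cohort multipliers; names
#'   are bin labels like `"1930-1939"`.
#' @param g_period named positive numeric vector of period multipliers; names
#'   are bin labels like `"1973-1977"`.
#' @param ref_cohort,ref_period labels of the reference bins (multiplier
#'   exactly 1).
#' @param cohort_starts,period_starts integer start years of the bins, same
#'   order as the multiplier vectors.
#' @param cohort_ends,period_ends integer end years (inclusive).
#' @return An object of class `apc_params`.
#' @export
apc_params <- function(g_cohort, g_period, ref_cohort, ref_period,
                       cohort_starts, cohort_ends,
                       period_starts, period_ends) {
  if (any(g_cohort <= 0) || any(g_period <= 0))
    stop("APC multipliers must be positive", call. = FALSE)
  if (!ref_cohort %in% names(g_cohort) || !ref_period %in% names(g_period))
    stop("reference bins must be among the bin labels", call. = FALSE)
  if (g_cohort[[ref_cohort]] != 1 || g_period[[ref_period]] != 1)
    stop("reference-bin multipliers must equal 1", call. = FALSE)
  structure(list(g_cohort = g_cohort, g_period = g_period,
                 ref_cohort = ref_cohort, ref_period = ref_period,
                 cohort_starts = cohort_starts, cohort_ends = cohort_ends,
                 period_starts = period_starts, period_ends = period_ends),
            class = "apc_params")
}

#' @export
print.apc_params <- function(x, ...) {
  cat("APC multipliers (reference bins:", x$ref_cohort, "/", x$ref_period, ")\n")
  cat("cohorts:\n"); print(round(x$g_cohort, 4))
  cat("periods:\n"); print(round(x$g_period, 4))
  invisible(x)
}

# decade / quinquennial bin construction; a trailing bin shorter than the
# width is merged into its predecessor (e.g. 1998-2003 for a 1973-2003 panel)
.make_bins <- function(lo, hi, width, align_decade = FALSE) {
  start0 <- if (align_decade) (lo %/% width) * width else lo
  starts <- seq(start0, hi, by = width)
  ends <- c(starts[-1] - 1L, hi)
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1) < width) {
    ends[length(ends) - 1] <- hi
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  list(starts = as.integer(starts), ends = as.integer(ends),
       labels = sprintf("%d-%d", starts, ends))
}

.bin_index <- function(values, bins, what) {
  idx <- findInterval(values, c(bins$starts, bins$ends[length(bins$ends)] + 1L))
  if (any(idx < 1 | idx > length(bins$starts))) {
    bad <- values[idx < 1 | idx > length(bins$starts)][1]
    stop("no ", what, " bin covering year ", bad, call. = FALSE)
  }
  idx
}

#' Incidence rate under the age-period-cohort embedding
#'
#' Marginal frailty-Weibull hazard times the sex and race relative risks and
#' the cohort and period multipliers of the observation cell. The parametric
#' period trend (`f_year`) is disabled by the substitution and ignored.
#'
#' @inheritParams model2_rate
#' @param apc an [apc_params()] object; the birth year `year - age` must fall
#'   in a defined cohort bin and `year` in a defined period bin.
#' @return Rate per person-year.
#' @export
apc_rate <- function(age, profile, params, cov, apc) {
  stopifnot(inherits(apc, "apc_params"))
  lam <- frailty_marginal_hazard(age, params)
  birth <- as.integer(floor(profile$year - age + 0.5))
  cb <- list(starts = apc$cohort_starts, ends = apc$cohort_ends)
  pb <- list(starts = apc$period_starts, ends = apc$period_ends)
  gi <- apc$g_cohort[.bin_index(birth, cb, "cohort")]
  gp <- apc$g_period[.bin_index(profile$year, pb, "period")]
  lam * cov$r_sex^profile$female * cov$r_race^profile$african_american *
    unname(gi) * unname(gp)
}

#' Fit the age-period-cohort extension of the model
#'
#' Joint estimation of the baseline frailty-Weibull parameters, the sex and
#' race relative risks, and log-scale cohort/period multipliers with the
#' reference bins (those containing the panel midpoint) fixed at 1. Used to
#' test the stability of the m-stage estimate against nonparametric secular
#' structure: compare `estimates["m"]` with the [fit_model2()] value.
#'
#' @inheritParams fit_model2
#' @param cohort_width birth-cohort bin width in years (default 10).
#' @param period_width calendar-period bin width in years (default 5).
#' @param start_from optional `mstage_fit` from [fit_model2()]; its baseline
#'   and relative-risk estimates seed the first optimizer start.
#' @return An object of class `mstage_fit` with an `apc` element holding the
#'   fitted [apc_params()].
#' @export
fit_apc <- function(table, config = fit_config(), cohort_width = 10L,
                    period_width = 5L, start_from = NULL) {
  df <- .fit_frame(table, config$z)
  birth <- df$year - df$age
  cb <- .make_bins(min(birth), max(birth), cohort_width, align_decade = TRUE)
  pb <- .make_bins(min(df$year), max(df$year), period_width)
  if (length(pb$starts) < 3 || length(cb$starts) < 4)
    stop("panel too narrow: need >= 3 period bins and >= 4 cohort bins",
         call. = FALSE)
  ci <- .bin_index(birth, cb, "cohort")
  pi <- .bin_index(df$year, pb, "period")

  mid_year <- floor(mean(range(df$year)))
  mid_birth <- mid_year - floor(mean(range(df$age)))
  ref_ci <- .bin_index(mid_birth, cb, "cohort")
  ref_pi <- .bin_index(mid_year, pb, "period")

  lg_c_names <- paste0("lg_c_", cb$starts[-ref_ci])
  lg_p_names <- paste0("lg_p_", pb$starts[-ref_pi])
  nonref_c <- seq_along(cb$starts)[-ref_ci]
  nonref_p <- seq_along(pb$starts)[-ref_pi]

  notes <- character()
  fix <- config$fix
  if (length(unique(df$female)) < 2 && !("r_sex" %in% names(fix))) {
    fix <- c(fix, r_sex = 1)
    notes <- c(notes, "r_sex unidentifiable (single-sex panel); fixed at 1")
  }
  if (length(unique(df$african_american)) < 2 && !("r_race" %in% names(fix))) {
    fix <- c(fix, r_race = 1)
    notes <- c(notes, "r_race unidentifiable (single-race panel); fixed at 1")
  }
  config$fix <- fix

  ux <- unique(df$x); ix <- match(df$x, ux)
  fem1 <- df$female + 1L; aa1 <- df$african_american + 1L
  nC <- length(cb$starts); nP <- length(pb$starts)
  rate_fn <- function(th) {
    lam <- .hazard_try(ux, th[["m"]], th[["c"]], th[["sigma"]], th[["n"]])[ix]
    lgc <- numeric(nC); lgc[nonref_c] <- th[lg_c_names]
    lgp <- numeric(nP); lgp[nonref_p] <- th[lg_p_names]
    lam * c(1, th[["r_sex"]])[fem1] * c(1, th[["r_race"]])[aa1] *
      exp(lgc[ci] + lgp[pi])
  }

  pooled <- .collapse_by_age(table, config$z)
  if (!is.null(start_from)) {
    stopifnot(inherits(start_from, "mstage_fit"))
    e <- start_from$estimates
    init <- c(m = e[["m"]], c = e[["c"]], sigma = e[["sigma"]], n = e[["n"]],
              r_sex = if ("r_sex" %in% names(e)) e[["r_sex"]] else 1,
              r_race = if ("r_race" %in% names(e)) e[["r_race"]] else 1)
  } else {
    init <- c(.init_baseline(pooled$x, pooled$rate), .init_covariates(df)[1:2])
  }
  init <- c(init, stats::setNames(numeric(length(lg_c_names)), lg_c_names),
            stats::setNames(numeric(length(lg_p_names)), lg_p_names))

  par_names <- c("m", "c", "sigma", "n", "r_sex", "r_race",
                 lg_c_names, lg_p_names)
  fit <- .fit_core(df, rate_fn, par_names, init, config,
                   model = "apc", notes = notes)

  g_cohort <- rep(1, nC); names(g_cohort) <- cb$labels
  g_cohort[nonref_c] <- exp(fit$estimates[lg_c_names])
  g_period <- rep(1, nP); names(g_period) <- pb$labels
  g_period[nonref_p] <- exp(fit$estimates[lg_p_names])
  fit$apc <- apc_params(g_cohort, g_period,
                        ref_cohort = cb$labels[ref_ci],
                        ref_period = pb$labels[ref_pi],
                        cohort_starts = cb$starts, cohort_ends = cb$ends,
                        period_starts = pb$starts, period_ends = pb$ends)
  fit
}

#' Tabulate APC multipliers
#'
#' @param apc an [apc_params()] object.
#' @return data.frame with columns `effect` (`cohort`/`period`), `bin`,
#'   `multiplier`, `reference`.
#' @export
apc_multiplier_table <- function(apc) {
  stopifnot(inherits(apc, "apc_params"))
  data.frame(
    effect = c(rep("cohort", length(apc$g_cohort)),
               rep("period", length(apc$g_period))),
    bin = c(names(apc$g_cohort), names(apc$g_period)),
    multiplier = unname(c(apc$g_cohort, apc$g_period)),
    reference = c(names(apc$g_cohort) == apc$ref_cohort,
                  names(apc$g_period) == apc$ref_period),
    row.names = NULL)
}
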