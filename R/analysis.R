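#' Histotype group summary of m-stage estimates
#'
#' Arithmetic mean and standard error of the mean (sample SD with the n-1
#' denominator over the square root of the group size) of per-cancer m-stage
#' estimates, by histotype, plus the non-reproductive-organ adenocarcinoma
#' subgroup.
#'
#' @param estimates data.frame with columns `cancer`, `histotype` (`"AC"` /
#'   `"SCC"`), `m` and optionally `se`.
#' @param nonreproductive_exclude cancer labels removed from the AC group to
#'   form the `AC_nonreproductive` subgroup. The default removes the
#'   breast (ductal and lobular), ovarian, cervical and prostate rows.
#' @return list of class `mstage_summary`: `per_cancer` (the input) and
#'   `group_stats` (data.frame with `group`, `mean`, `se`, `n`). Groups of
#'   size < 2 get `se = NA`.
#' @export
group_summary <- function(estimates,
                          nonreproductive_exclude = c(
                            "breast_ductal_ac", "breast_lobular_ac",
                            "ovarian_ac", "cervix_uteri_ac", "prostate_ac")) {
  need <- c("cancer", "histotype", "m")
  miss <- setdiff(need, names(estimates))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  one <- function(label, m) {
    n <- length(m)
    data.frame(group = label, mean = mean(m),
               se = if (n >= 2) stats::sd(m) / sqrt(n) else NA_real_, n = n)
  }
  groups <- list()
  for (h in unique(estimates$histotype))
    groups[[h]] <- one(h, estimates$m[estimates$histotype == h])
  nr <- estimates$histotype == "AC" &
    !(estimates$cancer %in% nonreproductive_exclude)
  if (any(nr))
    groups[["AC_nonreproductive"]] <- one("AC_nonreproductive",
                                          estimates$m[nr])
  structure(list(per_cancer = estimates,
                 group_stats = do.call(rbind, c(groups,
                                                list(make.row.names = FALSE)))),
            class = "mstage_summary")
}

#' @export
print.mstage_summary <- function(x, ...) {
  cat("m-stage group summary:\n")
  print(transform(x$group_stats, mean = round(mean, 2), se = round(se, 2)))
  invisible(x)
}

#' Compare mean m-stages between two histotype groups
#'
#' Difference of group means with a normal-approximation z-test treating the
#' group standard errors as known.
#'
#' @param summary an [group_summary()] result.
#' @param groups length-2 character vector of group labels to compare
#'   (first minus second).
#' @return list with `difference`, `se`, `z`, `p_value`.
#' @export
compare_histotypes <- function(summary, groups = c("SCC", "AC")) {
  stopifnot(inherits(summary, "mstage_summary"))
  gs <- summary$group_stats
  rows <- match(groups, gs$group)
  if (any(is.na(rows)))
    stop("group(s) not found: ",
         paste(groups[is.na(rows)], collapse = ", "), call. = FALSE)
  if (any(is.na(gs$se[rows])))
    stop("group standard errors unavailable", call. = FALSE)
  d <- gs$mean[rows[1]] - gs$mean[rows[2]]
  se <- sqrt(sum(gs$se[rows]^2))
  z <- d / se
  list(difference = d, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Correlation of m-stage estimates with a stage-at-diagnosis fraction
#'
#' Pearson correlation between per-cancer m-stage estimates and the
#' unweighted mean (over the available years) of one stage-at-diagnosis
#' fraction, with a t-transform p-value; optionally the unstaged mass is
#' first redistributed proportionally across the staged categories
#' ([redistribute_unstaged()]).
#'
#' @param estimates data.frame with columns `cancer` and `m`.
#' @param stage_tables a [stage_distribution()] covering the same cancers.
#' @param category one of `"in_situ"`, `"localized"`, `"regional"`,
#'   `"distant"`.
#' @param redistribute redistribute unstaged cases first?
#' @return list with `r`, `p_value`, `n` and the merged per-cancer table.
#' @export
correlate_mstages_stage <- function(estimates, stage_tables,
                                    category = "distant",
                                    redistribute = FALSE) {
  category <- match.arg(category, .stage_cats)
  stage_tables <- stage_distribution(stage_tables)
  if (redistribute) stage_tables <- redistribute_unstaged(stage_tables)
  fr <- stats::aggregate(stage_tables[[category]],
                         by = list(cancer = stage_tables$cancer), FUN = mean)
  names(fr)[2] <- "fraction"
  merged <- merge(estimates[c("cancer", "m")], fr, by = "cancer")
  if (nrow(merged) < 3)
    stop("need at least 3 cancers with both m and stage data", call. = FALSE)
  if (stats::sd(merged$m) == 0 || stats::sd(merged$fraction) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(merged$m, merged$fraction, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged),
       data = merged)
}

#' Sensitivity suite for the m-stage estimate
#'
#' Simulates one panel from the spec (extended by an open-ended 85+ age bin)
#' and refits it under seven perturbations of the analysis protocol:
#' shifting the minimum age by +5 years, including the 85+ bin, adding a
#' quadratic period term, re-binning ages to 5-year intervals, switching to
#' Poisson maximum likelihood, restricting to the middle third of the
#' calendar window, and replacing the parametric trend by the
#' age-period-cohort embedding. Each scenario reports the shift of the
#' fitted `m` relative to the base fit and whether it stays below the
#' stability threshold.
#'
#' @param spec a [cohort_spec()] without APC structure.
#' @param config a [fit_config()].
#' @param scenarios subset of the seven scenario names.
#' @param threshold stability threshold on `|delta m|` in stages.
#' @param ref_year period-trend anchor passed to [fit_model2()].
#' @return list with `base_fit`, `fits` (per-scenario `mstage_fit`s) and
#'   `report` (data.frame with `scenario`, `m`, `delta_m`, `delta_se`,
#'   `stable`, `converged`).
#' @export
sensitivity_suite <- function(spec, config = fit_config(),
                              scenarios = c("min_age_shift", "drop_85plus",
                                            "quadratic_trend",
                                            "five_year_bins", "mle_vs_wnls",
                                            "period_stratified", "apc"),
                              threshold = 1.5, ref_year = 1988L) {
  stopifnot(inherits(spec, "cohort_spec"))
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  spec85 <- spec
  spec85$ages <- c(spec$ages, 85L)
  panel <- simulate_panel(spec85)
  base_tab <- filter_min_age(panel)
  base <- fit_model2(base_tab, config, ref_year = ref_year)
  m0 <- base$estimates[["m"]]; se0 <- base$se[["m"]]

  run <- function(name) {
    f <- tryCatch(switch(name,
      min_age_shift = fit_model2(
        filter_min_age(panel, min_age = attr(panel, "min_age") + 5L),
        config, ref_year = ref_year),
      drop_85plus = fit_model2(
        filter_min_age(panel, include_85plus = TRUE), config,
        ref_year = ref_year),
      quadratic_trend = fit_model2(base_tab, config, ref_year = ref_year,
                                   quadratic = TRUE),
      five_year_bins = fit_model2(bin_ages(base_tab, 5), config,
                                  ref_year = ref_year),
      mle_vs_wnls = {
        cfg <- config; cfg$method <- "mle"
        fit_model2(base_tab, cfg, ref_year = ref_year)
      },
      period_stratified = {
        yr <- sort(unique(base_tab$year))
        mid <- yr[yr >= stats::quantile(yr, 1 / 3) &
                    yr <= stats::quantile(yr, 2 / 3)]
        sub <- .rebuild_table(
          as.data.frame(base_tab)[base_tab$year %in% mid, ], base_tab)
        fit_model2(sub, config, ref_year = ref_year)
      },
      apc = fit_apc(base_tab, config, start_from = base)),
      error = function(e) NULL)
    if (is.null(f)) {
      return(list(fit = NULL, row = data.frame(
        scenario = name, m = NA_real_, delta_m = NA_real_,
        delta_se = NA_real_, stable = NA, converged = FALSE)))
    }
    dm <- f$estimates[["m"]] - m0
    list(fit = f, row = data.frame(
      scenario = name, m = f$estimates[["m"]], delta_m = dm,
      delta_se = sqrt(se0^2 + f$se[["m"]]^2),
      stable = abs(dm) <= threshold, converged = f$converged))
  }
  runs <- lapply(scenarios, run)
  fits <- lapply(runs, `[[`, "fit")
  names(fits) <- scenarios
  list(base_fit = base, fits = fits,
       report = do.call(rbind, lapply(runs, `[[`, "row")))
}

#' Dot plot of m-stage estimates by histotype
#'
#' @param estimates data.frame with columns `cancer`, `histotype`, `m` and
#'   optionally `se` (error bars of +/- 1 SE).
#' @return A ggplot object.
#' @export
plot_mstages <- function(estimates) {
  est <- estimates[order(estimates$histotype, estimates$m), ]
  est$cancer <- factor(est$cancer, levels = est$cancer)
  p <- ggplot2::ggplot(est, ggplot2::aes(x = m, y = cancer,
                                         shape = histotype)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(AC = 16, SCC = 1)) +
    ggplot2::labs(x = "estimated number of m-stages", y = NULL,
                  shape = "histotype") +
    ggplot2::theme_minimal()
  if ("se" %in% names(est)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = m - se, xmax = m + se), height = 0.2)
  }
  p
}
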