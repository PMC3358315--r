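#' Simulate bundled-panel fixtures to CSV
#'
#' Generates synthetic incidence panels from the bundled per-cancer
#' parameter rows ([seer_cancer_parameters()]) and writes each as an incidence
#' CSV plus a JSON provenance sidecar (generating parameters, seed, package
#' version).
#'
#' @param fixture a cancer label from [seer_cancer_parameters()], or `"all"`.
#' @param seed integer seed; fixture `i` of the library uses `seed + i`.
#' @param out_dir output directory (created if missing).
#' @param years,exposure panel layout passed to [spec_from_parameters()].
#' @return Invisibly, the paths of the written CSV files.
#' @export
run_simulate <- function(fixture, seed = 1L, out_dir = ".",
                         years = 1973:2003, exposure = 2e5) {
  tab <- seer_cancer_parameters()
  if (!identical(fixture, "all") && !fixture %in% tab$cancer)
    stop("unknown fixture '", fixture, "'; valid names: all, ",
         paste(tab$cancer, collapse = ", "), call. = FALSE)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  rows <- if (identical(fixture, "all")) seq_len(nrow(tab)) else
    which(tab$cancer == fixture)
  paths <- character(0)
  for (i in rows) {
    spec <- spec_from_parameters(tab[i, ], years = years,
                                 exposure = exposure, seed = seed + i)
    panel <- simulate_panel(spec)
    path <- file.path(out_dir, paste0(tab$cancer[i], ".csv"))
    write_incidence_csv(panel, path)
    side <- list(cancer = tab$cancer[i], histotype = tab$histotype[i],
                 params = as.list(tab[i, setdiff(names(tab), c("cancer", "histotype"))]),
                 seed = seed + i, years = range(years), exposure = exposure,
                 version = as.character(utils::packageVersion("mstagefrailty")))
    jsonlite::write_json(side, file.path(out_dir, paste0(tab$cancer[i], "_spec.json")),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Fit a model to an incidence CSV and write reports
#'
#' Reads an incidence panel, applies the minimum-age rule, fits the chosen
#' model and writes a JSON fit report plus a fitted-curve CSV.
#'
#' @param input path to an incidence CSV ([read_incidence_csv()]).
#' @param model `"model2"` (covariate-generalized fit over all cells),
#'   `"frailty_weibull"` (pooled single-pattern fit), `"weibull"` or
#'   `"armitage_doll"` (homogeneous comparators, pooled).
#' @param method `"wnls"` or `"mle"`.
#' @param out_dir output directory (created if missing).
#' @param min_age minimum analysis age (default: smallest age present).
#' @param max_age optional maximum age retained (e.g. 75 to restrict the
#'   fit to the region below the late-age downturn).
#' @param multistart,seed optimizer settings, see [fit_config()].
#' @return The `mstage_fit`, invisibly.
#' @export
run_fit <- function(input, model = c("model2", "frailty_weibull", "weibull",
                                     "armitage_doll"),
                    method = c("wnls", "mle"), out_dir = ".",
                    min_age = NULL, max_age = NULL, multistart = 8L,
                    seed = 1L) {
  model <- match.arg(model)
  method <- match.arg(method)
  tab <- read_incidence_csv(input, min_age = min_age)
  tab <- filter_min_age(tab)
  if (!is.null(max_age))
    tab <- .rebuild_table(as.data.frame(tab)[tab$age <= max_age, ], tab)
  cfg <- fit_config(method = method, multistart = multistart, seed = seed)
  fit <- switch(model,
    model2 = fit_model2(tab, cfg),
    frailty_weibull = fit_model1(tab, cfg),
    weibull = compare_models(tab, "weibull", cfg)$fits[[1]],
    armitage_doll = compare_models(tab, "armitage_doll", cfg)$fits[[1]])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stem <- tools::file_path_sans_ext(basename(input))
  jsonlite::write_json(fit_report(fit),
                       file.path(out_dir, paste0(stem, "_fit.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(fitted_curve(fit),
                   file.path(out_dir, paste0(stem, "_curve.csv")),
                   row.names = FALSE)
  invisible(fit)
}

#' Summarize per-cancer m-stage estimates and compare histotypes
#'
#' Takes a per-cancer estimate table (or a CSV path with columns `cancer`,
#' `histotype`, `m`, optionally `se`), writes the histotype group summary
#' and the SCC-vs-AC comparison as JSON, optionally the correlation with a
#' stage-at-diagnosis fraction, and a dot plot of the estimates.
#'
#' @param estimates data.frame or CSV path.
#' @param out_dir output directory (created if missing).
#' @param stage_tables optional [stage_distribution()] for the correlation
#'   analysis.
#' @param plot_file file name of the dot plot written into `out_dir`
#'   (`NULL` to skip).
#' @return The [group_summary()], invisibly.
#' @export
run_analyze <- function(estimates, out_dir = ".", stage_tables = NULL,
                        plot_file = "mstages.png") {
  if (is.character(estimates)) estimates <- utils::read.csv(estimates)
  if (nrow(estimates) < 2) stop("need at least 2 fitted cancers", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summ <- group_summary(estimates)
  out <- list(group_stats = summ$group_stats)
  if (all(c("SCC", "AC") %in% summ$group_stats$group)) {
    out$scc_vs_ac <- compare_histotypes(summ)
  } else {
    warning("single histotype present: comparison skipped", call. = FALSE)
  }
  if (!is.null(stage_tables)) {
    out$distant_correlation <- correlate_mstages_stage(
      estimates, stage_tables, "distant")[c("r", "p_value", "n")]
  }
  jsonlite::write_json(out, file.path(out_dir, "group_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(plot_file)) {
    p <- plot_mstages(estimates)
    ggplot2::ggsave(file.path(out_dir, plot_file), p,
                    width = 6, height = 5, dpi = 150)
  }
  invisible(summ)
}
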