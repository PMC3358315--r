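#' Construct an incidence table
#'
#' A long-format panel of registry-style incidence data: one row per
#' (age, year, sex, race) cell with a diagnosis count and the person-years of
#' exposure. Ages are 1-year bins labeled by their start; rates are evaluated
#' at bin midpoints.
#'
#' @param records data.frame with columns `age`, `year`, `female`,
#'   `african_american`, `count`, `person_years`.
#' @param cancer_label free-text cancer identifier.
#' @param histotype one of `"AC"`, `"SCC"`, `"other"`.
#' @param min_age minimum age retained by [filter_min_age()]; defaults to the
#'   smallest age present.
#' @param bin_width age-bin width in years (1 for raw panels).
#' @return data.frame of class `incidence_table` with attributes
#'   `cancer_label`, `histotype`, `min_age`, `bin_width`.
#' @export
incidence_table <- function(records, cancer_label = "unspecified",
                            histotype = c("other", "AC", "SCC"),
                            min_age = NULL, bin_width = 1L) {
  histotype <- match.arg(histotype)
  need <- c("age", "year", "female", "african_american", "count", "person_years")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  records <- as.data.frame(records)[need]
  if (any(records$count < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(records$person_years <= 0))
    stop("person-years must be positive", call. = FALSE)
  if (any(records$age < 0 | records$age > 85))
    stop("ages must lie in [0, 85]", call. = FALSE)
  if (!all(records$female %in% c(0, 1)) ||
      !all(records$african_american %in% c(0, 1)))
    stop("sex/race indicators must be 0 or 1", call. = FALSE)
  key <- with(records, paste(age, year, female, african_american))
  if (anyDuplicated(key))
    stop("duplicate (age, year, sex, race) cells", call. = FALSE)
  if (is.null(min_age)) min_age <- min(records$age)
  structure(records,
            cancer_label = cancer_label, histotype = histotype,
            min_age = as.integer(min_age), bin_width = as.numeric(bin_width),
            class = c("incidence_table", "data.frame"))
}

.rebuild_table <- function(records, template, min_age = NULL, bin_width = NULL) {
  incidence_table(records,
                  cancer_label = attr(template, "cancer_label"),
                  histotype = attr(template, "histotype"),
                  min_age = if (is.null(min_age)) attr(template, "min_age") else min_age,
                  bin_width = if (is.null(bin_width)) attr(template, "bin_width") else bin_width)
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("incidence table: %s (%s), %d cells, ages %d-%d, years %d-%d\n",
              attr(x, "cancer_label"), attr(x, "histotype"), nrow(x),
              min(x$age), max(x$age), min(x$year), max(x$year)))
  NextMethod()
}

#' Rate and Wilson-adjusted variance of an incidence rate
#'
#' Treats the rate as a binomial proportion `count / person_years` and
#' estimates its variance from the Wilson score interval:
#' \eqn{\tilde p = (k + z^2/2)/(N + z^2)}, variance
#' \eqn{\tilde p (1 - \tilde p) / (N + z^2)}. The variance stays strictly
#' positive at zero counts, so every cell of a 1-year-binned panel gets a
#' finite weight in weighted least squares.
#'
#' @param count diagnosis count(s), non-negative.
#' @param person_years exposure(s), positive.
#' @param z normal quantile of the score interval (default 1.96).
#' @return data.frame with columns `rate` and `variance`.
#' @export
rate_and_variance <- function(count, person_years, z = 1.96) {
  if (any(person_years <= 0))
    stop("person-years must be positive", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  if (z <= 0) stop("'z' must be positive", call. = FALSE)
  p_tilde <- (count + z^2 / 2) / (person_years + z^2)
  data.frame(rate = count / person_years,
             variance = p_tilde * (1 - p_tilde) / (person_years + z^2))
}

#' Apply the minimum-age rule and the 85+ exclusion
#'
#' Removes records below the table's minimum analysis age (the smallest age at
#' which the registry pattern is considered reliable for the cancer site) and,
#' unless `include_85plus`, the open-ended 85+ bin.
#'
#' @param table an [incidence_table()].
#' @param min_age override of the table's `min_age` attribute.
#' @param include_85plus keep records with `age >= 85`?
#' @return A filtered `incidence_table`.
#' @export
filter_min_age <- function(table, min_age = NULL, include_85plus = FALSE) {
  stopifnot(inherits(table, "incidence_table"))
  if (is.null(min_age)) min_age <- attr(table, "min_age")
  keep <- table$age >= min_age
  if (!include_85plus) keep <- keep & table$age < 85
  out <- as.data.frame(table)[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no records remain after age filtering", call. = FALSE)
  .rebuild_table(out, table, min_age = min_age)
}

#' Re-bin ages into wider intervals
#'
#' Sums counts and person-years within consecutive age bins of the given
#' width; bins are labeled by their start age. A trailing partial bin (when
#' the width does not divide the age range) is retained and flagged through
#' the `partial_bins` attribute.
#'
#' @param table an [incidence_table()] with 1-year bins.
#' @param width bin width in years (1 returns the table unchanged; the
#'   stratified sensitivity analysis uses 5).
#' @return An `incidence_table` with `bin_width = width`.
#' @export
bin_ages <- function(table, width) {
  stopifnot(inherits(table, "incidence_table"))
  if (!is.numeric(width) || length(width) != 1L || width < 1)
    stop("'width' must be a positive bin width", call. = FALSE)
  if (width == 1) return(table)
  a0 <- min(table$age)
  bin <- a0 + ((table$age - a0) %/% width) * width
  agg <- stats::aggregate(
    cbind(count, person_years) ~ bin + year + female + african_american,
    data = transform(as.data.frame(table), bin = bin), FUN = sum)
  names(agg)[names(agg) == "bin"] <- "age"
  agg <- agg[c("age", "year", "female", "african_american", "count", "person_years")]
  out <- .rebuild_table(agg, table, bin_width = width)
  span <- max(table$age) - a0 + 1
  if (span %% width != 0) attr(out, "partial_bins") <- TRUE
  out
}

#' Stage-at-diagnosis distribution table
#'
#' Validates a data.frame of stage-at-diagnosis percentages with columns
#' `cancer`, `year`, `in_situ`, `localized`, `regional`, `distant`,
#' `unstaged`. Fractions are percentages in \[0, 100\]; the per-row sum may
#' not exceed 100 beyond rounding slack.
#'
#' @param x data.frame in the stage-table layout.
#' @return The validated data.frame, class `stage_distribution`.
#' @export
stage_distribution <- function(x) {
  need <- c("cancer", "year", .stage_cats, "unstaged")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x)[need]
  fr <- as.matrix(x[c(.stage_cats, "unstaged")])
  if (any(!is.finite(fr))) stop("stage fractions must be numeric", call. = FALSE)
  if (any(fr < 0) || any(fr > 100))
    stop("stage fractions must lie in [0, 100]", call. = FALSE)
  if (any(rowSums(fr) > 100 + 0.5))
    stop("stage fractions sum above 100 beyond rounding slack", call. = FALSE)
  class(x) <- c("stage_distribution", "data.frame")
  x
}

.stage_cats <- c("in_situ", "localized", "regional", "distant")

#' Redistribute unstaged cases across observed stages
#'
#' Reallocates the unstaged percentage proportionally to the staged
#' categories, assuming unobserved stages are distributed like the staged
#' cases of the same row; the total is preserved and `unstaged` becomes 0.
#'
#' @param dist a [stage_distribution()] (one or more rows).
#' @return A `stage_distribution` with `unstaged = 0`.
#' @export
redistribute_unstaged <- function(dist) {
  dist <- stage_distribution(dist)
  staged <- as.matrix(dist[.stage_cats])
  tot <- rowSums(staged)
  if (any(tot <= 0 & dist$unstaged > 0))
    stop("cannot redistribute: all staged fractions are zero", call. = FALSE)
  scale <- ifelse(tot > 0, (tot + dist$unstaged) / tot, 1)
  dist[.stage_cats] <- staged * scale
  dist$unstaged <- 0
  dist
}

#' Read / write incidence panels as CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with header
#' `cancer,histotype,age,year,sex,race,count,person_years`; `sex` is
#' `male`/`female` and `race` is `caucasian`/`african_american`.
#'
#' @param path file path.
#' @param min_age optional minimum analysis age to attach on read (defaults
#'   to the smallest age present).
#' @return `read_incidence_csv()` returns an [incidence_table()];
#'   `write_incidence_csv()` returns `path` invisibly.
#' @export
read_incidence_csv <- function(path, min_age = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cancer", "histotype", "age", "year", "sex", "race",
            "count", "person_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed incidence CSV, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$sex %in% c("male", "female"))
  if (length(bad))
    stop("malformed incidence CSV: unknown 'sex' at data row ", bad[1],
         call. = FALSE)
  bad <- which(!df$race %in% c("caucasian", "african_american"))
  if (length(bad))
    stop("malformed incidence CSV: unknown 'race' at data row ", bad[1],
         call. = FALSE)
  rec <- data.frame(age = df$age, year = df$year,
                    female = as.integer(df$sex == "female"),
                    african_american = as.integer(df$race == "african_american"),
                    count = df$count, person_years = df$person_years)
  incidence_table(rec, cancer_label = df$cancer[1],
                  histotype = if (df$histotype[1] %in% c("AC", "SCC"))
                    df$histotype[1] else "other",
                  min_age = min_age)
}

#' @rdname read_incidence_csv
#' @param table an [incidence_table()].
#' @export
write_incidence_csv <- function(table, path) {
  stopifnot(inherits(table, "incidence_table"))
  df <- data.frame(cancer = attr(table, "cancer_label"),
                   histotype = attr(table, "histotype"),
                   age = table$age, year = table$year,
                   sex = ifelse(table$female == 1, "female", "male"),
                   race = ifelse(table$african_american == 1,
                                 "african_american", "caucasian"),
                   count = table$count, person_years = table$person_years)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write stage-at-diagnosis tables as CSV
#'
#' Stage tables use the columns of [stage_distribution()]. Missing cells
#' (empty or dash, as in printed registry tables) are read as 0 with a
#' warning.
#'
#' @param path file path.
#' @return `read_stage_csv()` returns a [stage_distribution()];
#'   `write_stage_csv()` returns `path` invisibly.
#' @export
read_stage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "-", "–", "NA"))
  cols <- c(.stage_cats, "unstaged")
  n_missing <- sum(is.na(df[cols]))
  if (n_missing > 0) {
    warning(n_missing, " missing stage cell(s) read as 0", call. = FALSE)
    df[cols][is.na(df[cols])] <- 0
  }
  stage_distribution(df)
}

#' @rdname read_stage_csv
#' @param dist a [stage_distribution()].
#' @export
write_stage_csv <- function(dist, path) {
  dist <- stage_distribution(dist)
  utils::write.csv(as.data.frame(dist), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stage-at-diagnosis fractions bundled with the package
#'
#' Registry-style stage-at-diagnosis percentages (in situ, localized,
#' regional, distant, unstaged) for the 26 studied cancer sites, at the first
#' and last observation years (plus coding-change years where relevant).
#'
#' @return A [stage_distribution()] data.frame.
#' @export
seer_stage_distributions <- function() {
  path <- system.file("extdata", "stage_distributions_seer.csv",
                      package = "mstagefrailty", mustWork = TRUE)
  suppressWarnings(read_stage_csv(path))
}
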