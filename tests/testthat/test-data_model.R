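test_that("Wilson-adjusted rate variance stays positive and hits the limits", {
  # zero-count cell: variance from the stated formula, evaluated directly
  z <- 1.96
  p_tilde <- (0 + z^2 / 2) / (1000 + z^2)
  rv <- rate_and_variance(0, 1000)
  expect_equal(rv$rate, 0)
  expect_equal(rv$variance, p_tilde * (1 - p_tilde) / (1000 + z^2))
  expect_equal(rv$variance, 1.903e-6, tolerance = 1e-3)
  # large-count binomial limit p(1-p)/N
  rv2 <- rate_and_variance(5e5, 1e6)
  expect_equal(rv2$variance, 0.25 / 1e6, tolerance = 1e-4)
  # weights finite and positive for every count including zero
  rv3 <- rate_and_variance(c(0, 1, 10, 1e4), rep(2e5, 4))
  expect_true(all(is.finite(1 / rv3$variance)) && all(rv3$variance > 0))
  expect_error(rate_and_variance(3, 0), "person-years")
})

test_that("minimum-age filtering keeps the documented bin counts", {
  rec <- expand.grid(age = 0:84, year = 1988,
                     female = 0:1, african_american = 0)
  rec$count <- 1; rec$person_years <- 1e5
  tab <- incidence_table(rec, min_age = 30)
  kept <- filter_min_age(tab)
  expect_equal(nrow(kept), 55 * 2)              # ages 30..84 per stratum
  expect_equal(sort(unique(kept$age)), 30:84)
  expect_equal(nrow(filter_min_age(tab, min_age = 0)), nrow(tab))
  expect_error(filter_min_age(tab, min_age = 85), "no records")
  # 85+ handling
  rec85 <- rbind(rec, data.frame(age = 85, year = 1988, female = 0,
                                 african_american = 0, count = 1,
                                 person_years = 1e5))
  tab85 <- incidence_table(rec85, min_age = 30)
  expect_false(85 %in% filter_min_age(tab85)$age)
  expect_true(85 %in% filter_min_age(tab85, include_85plus = TRUE)$age)
})

test_that("age re-binning conserves counts and exposure", {
  rec <- expand.grid(age = 30:84, year = 1987:1988, female = 0,
                     african_american = 0)
  set.seed(3); rec$count <- rpois(nrow(rec), 40)
  rec$person_years <- 1e5
  tab <- incidence_table(rec, min_age = 30)
  expect_identical(bin_ages(tab, 1), tab)
  b5 <- bin_ages(tab, 5)
  expect_equal(sum(b5$count), sum(tab$count))
  expect_equal(sum(b5$person_years), sum(tab$person_years))
  expect_equal(length(unique(b5$age)), 11)
  expect_equal(attr(b5, "bin_width"), 5)
  # merged rate equals count-sum over exposure-sum (two 1-year cells)
  two <- incidence_table(data.frame(age = 30:31, year = 1988, female = 0,
                                    african_american = 0, count = c(3, 7),
                                    person_years = 1e5), min_age = 30)
  expect_equal(bin_ages(two, 2)$count / bin_ages(two, 2)$person_years,
               10 / 2e5)
  # trailing partial bin flagged when the width does not divide the range
  b7 <- bin_ages(tab, 7)
  expect_true(isTRUE(attr(b7, "partial_bins")))
})

test_that("unstaged redistribution preserves totals and scales stages", {
  stages <- seer_stage_distributions()
  lung03 <- stages[stages$cancer == "lung_scc" & stages$year == 2003, ]
  out <- redistribute_unstaged(lung03)
  expect_equal(out$distant, 24.1 * (95.5 + 4.5) / 95.5, tolerance = 1e-10)
  expect_equal(out$distant, 25.24, tolerance = 1e-3)
  expect_equal(out$unstaged, 0)
  # conservation of the total
  tot_before <- with(lung03, in_situ + localized + regional + distant + unstaged)
  tot_after <- with(out, in_situ + localized + regional + distant + unstaged)
  expect_equal(tot_before, tot_after, tolerance = 1e-9)
  # identity when nothing is unstaged
  z <- lung03; z$unstaged <- 0
  expect_equal(redistribute_unstaged(z), stage_distribution(z))
  bad <- data.frame(cancer = "x", year = 2000, in_situ = 0, localized = 0,
                    regional = 0, distant = 0, unstaged = 10)
  expect_error(redistribute_unstaged(bad), "staged")
})

test_that("incidence CSV round-trips counts and exposures losslessly", {
  spec <- cohort_spec(lung_ac_params(), ages = 40:60, years = 1990:1992,
                      exposure = 12345.5, seed = 5, cancer_label = "lung_ac",
                      histotype = "AC", min_age = 40)
  tab <- simulate_panel(spec)
  path <- tempfile(fileext = ".csv")
  write_incidence_csv(tab, path)
  back <- read_incidence_csv(path, min_age = 40)
  expect_identical(back$count, tab$count)
  expect_equal(back$person_years, tab$person_years)
  for (col in c("age", "year", "female", "african_american"))
    expect_equal(as.numeric(back[[col]]), as.numeric(tab[[col]]))
  expect_equal(attr(back, "cancer_label"), "lung_ac")
  # malformed input names the offending column
  bad <- tempfile(fileext = ".csv")
  writeLines("cancer,age,year,count\nx,30,1990,1", bad)
  expect_error(read_incidence_csv(bad), "missing column")
})

test_that("stage CSV reading zero-fills printed missing cells with a warning", {
  expect_warning(
    read_stage_csv(system.file("extdata", "stage_distributions_seer.csv",
                               package = "mstagefrailty")),
    "missing stage cell")
  stages <- seer_stage_distributions()
  expect_s3_class(stages, "stage_distribution")
  expect_equal(length(unique(stages$cancer)), 26)
  # printed dash cells arrive as 0
  lung83 <- stages[stages$cancer == "lung_ac" & stages$year == 1983, ]
  expect_equal(lung83$in_situ, 0)
  # round-trip
  path <- tempfile(fileext = ".csv")
  write_stage_csv(stages, path)
  expect_equal(as.data.frame(read_stage_csv(path)), as.data.frame(stages))
})
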