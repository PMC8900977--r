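test_that("percent reduction reproduces the dose-response arithmetic", {
  # spoon rows: numerator / 18.17 denominator
  expect_equal(percent_reduction(3.71, 18.17), 20.42)
  expect_equal(percent_reduction(3.55, 18.17), 19.54)
  expect_equal(percent_reduction(3.15, 18.17), 17.34)
  expect_equal(percent_reduction(3.04, 18.17), 16.73)
  # substitution rows
  expect_equal(percent_reduction(12.07, 18.17), 66.43)
  expect_equal(percent_reduction(11.89, 18.17), 65.44)
  expect_equal(percent_reduction(11.81, 18.17), 65.00)
  expect_equal(percent_reduction(11.74, 18.17), 64.61)
  expect_equal(percent_reduction(0, 5), 0)
  expect_error(percent_reduction(1, 0), "positive")
})

test_that("burden shares and relative errors are plain ratios", {
  expect_equal(round(burden_share(472.9, 3754), 1), 12.6)
  expect_equal(round(burden_share(472.9, 3754)), 13)
  expect_equal(burden_share(0, 10), 0)
  expect_equal(burden_share(10, 10), 100)
  expect_error(burden_share(1, 0), "positive")
  expect_equal(relative_error(100, 100), 0)
  expect_equal(relative_error(99.2, 100), -0.8)
  expect_equal(relative_error(107.7, 100), 7.7)
  expect_error(relative_error(5, 0), "nonzero")
  v <- validate_against(c(intake = 4.1), c(intake = 4.0))
  expect_equal(v$relative_error_pct, 2.5)
})

test_that("equity ratios are pairwise and reciprocal", {
  eq <- equity_ratio(c(north = 12, central = 15, south = 10))
  expect_equal(eq["north/south", "ratio"], 1.2)
  expect_equal(eq["north/south", "ratio"] * eq["south/north", "ratio"], 1)
  same <- equity_ratio(c(north = 3, central = 3, south = 3))
  expect_true(all(same$ratio == 1))
  expect_error(equity_ratio(c(north = 1, south = 0)), "positive")
})

test_that("two-decimal rounding is half-up", {
  expect_equal(percent_reduction(0.125, 100), 0.13)
  expect_equal(percent_reduction(16.725, 100), 16.73)
})

test_that("stratified summaries partition the totals", {
  w <- small_world()
  pop <- small_population()
  cmp <- compare_scenarios(pop, w$rates, w$trends,
                           list(scenario_spec("substitute",
                                              substitute_fraction = 0.95)),
                           seed = 13)
  for (by in c("sex", "region", "age_group", "province")) {
    s <- stratified_summary(cmp, by = by)
    expect_equal(sum(s$n), cmp$n)
    expect_equal(sum(s$baseline_attributable_daly), cmp$attributable_daly,
                 tolerance = 1e-9)
    expect_equal(sum(s$averted_daly),
                 cmp$burdens$none$daly -
                   cmp$burdens$substitute_0.95$daly,
                 tolerance = 1e-9)
  }
  s <- stratified_summary(cmp, by = "age_group")
  expect_true(all(s$stratum %in% c("0-39", "40-59", "60+")))
  expect_error(stratified_summary(cmp, by = "shoe_size"))
})

test_that("a single-stratum cohort's summary equals its total", {
  ts <- toy_setup(n = 800, usual_g = 4.5, incidence = 0.01,
                  case_fatality = 0.2, acm = 0.01)
  cmp <- compare_scenarios(ts$pop, ts$rates, ts$trends,
                           list(scenario_spec("spoon",
                                              spoon_sodium_mg = 197)),
                           seed = 19)
  s <- stratified_summary(cmp, by = "province", scenario = "spoon_197")
  expect_equal(nrow(s), 1)
  expect_equal(s$baseline_attributable_daly, cmp$attributable_daly,
               tolerance = 1e-9)
})

test_that("a cohort built to concentrate risk in midlife ranks 40-59 first", {
  # only the 40-59 band consumes above threshold, so all attributable
  # and averted burden must sit in that age group
  census <- data.frame(province = "Toyland", region = "north",
                       sex = "male",
                       age_band = c("20-24", "45-49", "70-74"),
                       count = c(100L, 100L, 100L))
  donors <- data.frame(
    province = "Toyland", sex = "male",
    age_band = c("20-24", "45-49", "70-74"),
    usual_sodium_g = c(1.0, 5.0, 1.0),
    share_added_salt = 0.7, share_soy_sauce = 0.1, share_msg = 0.05,
    share_fermented = 0.05, share_pickled = 0.05, share_other = 0.05)
  pop <- build_population(census, donors, n = 1500, seed = 5)
  ts <- toy_setup(n = 2)
  rates <- ts$rates
  rates$gca_incidence <- 0.004
  rates$gca_prevalence <- 0.5
  rates$gca_mortality <- 0.1  # case fatality 0.2
  trends <- data.frame(province = "Toyland", a = 3, b = 0,
                       constant_flag = TRUE, t0 = 2004)
  cmp <- compare_scenarios(pop, rates, trends,
                           list(scenario_spec("substitute",
                                              substitute_fraction = 0.95)),
                           seed = 77)
  s <- stratified_summary(cmp, by = "age_group")
  top <- s$stratum[which.max(s$averted_daly)]
  expect_equal(top, "40-59")
})
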