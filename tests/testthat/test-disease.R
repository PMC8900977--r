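test_that("linear relative risk behaves at and above the threshold", {
  expect_equal(relative_risk(1.5, 1.5, 0.2), 1.0)
  expect_equal(relative_risk(3.5, 1.5, 0.2), 1.4)
  expect_equal(relative_risk(0.5, 1.5, 0.2), 1.0)
  expect_equal(relative_risk(10, 1.5, 0), 1.0)
  expect_error(relative_risk(3, 1.5, -0.1), "nonnegative")
})

test_that("rate extrapolation follows the APC closed form and clamps", {
  expect_equal(extrapolate_rate(0.01, 0, 7), 0.01)
  expect_equal(extrapolate_rate(0.01, -2, 10), 0.01 * 0.98^10)
  expect_equal(extrapolate_rate(0.01, -2, 10), 0.008171, tolerance = 1e-4)
  expect_lte(extrapolate_rate(0.9, 5, 10), 1)
  expect_error(extrapolate_rate(1.2, 0, 1), "\\[0,1\\]")
})

test_that("certain mortality kills every living member of the stratum", {
  ts <- toy_setup(n = 100, acm = 1)
  step <- advance_year(ts$pop, ts$rates, disease_config(), 2010)
  expect_true(all(step$population$state == "dead"))
  expect_true(all(step$log$died))
})

test_that("no cancer arises with a zero slope and zero base rate", {
  ts <- toy_setup(n = 300, incidence = 0, rr_per_gram = 0)
  lg <- simulate_cohort(ts$pop, ts$rates, ts$trends, seed = 4)
  expect_equal(sum(lg$incident_gca), 0)
})

test_that("with all rates zeroed only age changes over 20 years", {
  ts <- toy_setup(n = 200, acm = 0, incidence = 0)
  lg <- simulate_cohort(ts$pop, ts$rates, ts$trends, seed = 6)
  expect_equal(sum(lg$died), 0)
  expect_equal(sum(lg$incident_gca), 0)
  last <- lg[lg$year == 2030, ]
  first <- lg[lg$year == 2010, ]
  expect_equal(nrow(last), nrow(first))
  expect_equal(last$age, first$age + 20L)
  expect_equal(last$state, first$state)
})

test_that("person-years are conserved: alive(y+1) = alive(y) - deaths(y)", {
  w <- small_world()
  pop <- small_population()
  lg <- simulate_cohort(pop, w$rates, w$trends, seed = 12)
  by_year <- split(lg, lg$year)
  yrs <- as.integer(names(by_year))
  for (i in seq_along(yrs)[-length(yrs)]) {
    expect_equal(nrow(by_year[[i + 1]]),
                 nrow(by_year[[i]]) - sum(by_year[[i]]$died))
  }
  # the state machine: dead is absorbing, at most one cancer onset
  expect_true(all(tapply(lg$incident_gca, lg$person_id, sum) <= 1))
  expect_false(any(lg$state == "dead"))
})

test_that("one-year incident counts match the binomial oracle", {
  # one stratum, base incidence 0.01, excess 2 g -> RR = 1.4
  ts <- toy_setup(n = 5000, usual_g = 3.5, tmrel = 1.5,
                  incidence = 0.01, rr_per_gram = 0.2)
  cfg <- disease_config(horizon = c(2010, 2011))
  step <- advance_year(ts$pop, ts$rates, cfg, 2010,
                       intake_g = ts$pop$usual_sodium_g)
  observed <- sum(step$log$incident_gca)
  p <- 0.01 * 1.4
  expected <- 5000 * p
  se <- sqrt(5000 * p * (1 - p))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("the exposure lag delays intervention effects by eight years", {
  ts <- toy_setup(n = 2000, usual_g = 5, tmrel = 1.5, incidence = 0.01,
                  rr_per_gram = 1.5)
  sub <- scenario_spec("substitute", substitute_fraction = 0.95)
  lg0 <- simulate_cohort(ts$pop, ts$rates, ts$trends, seed = 21)
  lg1 <- simulate_cohort(ts$pop, ts$rates, ts$trends, sub, seed = 21)
  inc0 <- tapply(lg0$incident_gca, lg0$year, sum)
  inc1 <- tapply(lg1$incident_gca, lg1$year, sum)
  pre <- as.character(2010:2017)
  expect_equal(inc0[pre], inc1[pre])
  post <- as.character(2018:2030)
  expect_lt(sum(inc1[post]), sum(inc0[post]))
})

test_that("simulation is deterministic and coupling orders scenarios", {
  w <- small_world()
  pop <- small_population()
  spoon <- scenario_spec("spoon", spoon_sodium_mg = 788)
  lg1 <- simulate_cohort(pop, w$rates, w$trends, spoon, seed = 3)
  lg2 <- simulate_cohort(pop, w$rates, w$trends, spoon, seed = 3)
  expect_identical(as.data.frame(lg1), as.data.frame(lg2))
  # common random numbers: the intervention cannot create cases
  for (s in c(3, 14, 15)) {
    l_none <- simulate_cohort(pop, w$rates, w$trends, seed = s)
    l_spoon <- simulate_cohort(pop, w$rates, w$trends, spoon, seed = s)
    expect_lte(sum(l_spoon$incident_gca), sum(l_none$incident_gca))
  }
})

test_that("an empty population yields an empty log", {
  ts <- toy_setup(n = 1)
  empty <- ts$pop[0, ]
  attr(empty, "base_year") <- 2010
  lg <- simulate_cohort(empty, ts$rates, ts$trends, seed = 1)
  expect_equal(nrow(lg), 0)
})

test_that("missing rate strata are rejected by name", {
  ts <- toy_setup(n = 10)
  rates <- ts$rates[ts$rates$age_band != "40-44", ]
  expect_error(simulate_cohort(ts$pop, rates, ts$trends, seed = 1),
               "40-44")
})

test_that("incidence derivation balances prevalence in and out-flow", {
  inc <- derive_incidence(prev = 0.01, gca_mort = 0.002, acm = 0.02)
  # cf = 0.002 / 0.01 = 0.2; inc = 0.01 * 0.22 / 0.99
  expect_equal(inc, 0.01 * (0.02 + 0.2) / 0.99)
  expect_equal(derive_incidence(0, 0, 0.02), 0)
})
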