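test_that("daily sodium follows the composition arithmetic", {
  # 10 g of pure salt at 39,340 mg sodium / 100 g -> 3.934 g sodium
  recalls <- data.frame(person_id = "P1", survey_year = 2011L,
                        day_index = 1L, food_code = "SALT",
                        amount_g = 10)
  fct <- data.frame(food_code = "SALT", sodium_mg_per_100g = 39340,
                    source_category = "added_salt")
  usual <- estimate_usual_intake(recalls, fct)
  expect_equal(usual$person_mean_g, 3.934)
  expect_equal(usual$usual_sodium_g, 3.934)
  expect_equal(usual$share_added_salt, 1)
})

test_that("unresolvable food codes are rejected by name", {
  recalls <- data.frame(person_id = "P1", survey_year = 2011L,
                        day_index = 1L, food_code = "MYSTERY",
                        amount_g = 5)
  fct <- generate_fct()
  expect_error(estimate_usual_intake(recalls, fct), "MYSTERY")
})

test_that("shrinkage contracts person means toward the stratum mean", {
  set.seed(42)
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  pm <- rnorm(n, 4, 0.6)
  days <- data.frame(
    person_id = rep(ids, each = 3),
    survey_year = 2011L,
    day_index = rep(1:3, n),
    food_code = "SALT",
    amount_g = pmax(rep(pm, each = 3) + rnorm(3 * n, 0, 0.8), 0.2) /
      0.3934,
    stringsAsFactors = FALSE
  )
  fct <- data.frame(food_code = "SALT", sodium_mg_per_100g = 39340,
                    source_category = "added_salt")
  usual <- estimate_usual_intake(days, fct)
  sm <- mean(usual$person_mean_g)
  # usual lies between the person mean and the stratum mean
  lo <- pmin(usual$person_mean_g, sm) - 1e-9
  hi <- pmax(usual$person_mean_g, sm) + 1e-9
  expect_true(all(usual$usual_sodium_g >= lo & usual$usual_sodium_g <= hi))
  # spread contracts
  expect_lt(stats::var(usual$usual_sodium_g),
            stats::var(usual$person_mean_g))
})

test_that("zero within-person variance means no shrinkage", {
  ids <- sprintf("P%02d", 1:20)
  pm <- seq(2, 6, length.out = 20)
  days <- data.frame(person_id = rep(ids, each = 3), survey_year = 2011L,
                     day_index = rep(1:3, 20), food_code = "SALT",
                     amount_g = rep(pm, each = 3) / 0.3934,
                     stringsAsFactors = FALSE)
  fct <- data.frame(food_code = "SALT", sodium_mg_per_100g = 39340,
                    source_category = "added_salt")
  usual <- estimate_usual_intake(days, fct)
  expect_equal(usual$usual_sodium_g, usual$person_mean_g, tolerance = 1e-9)
})

test_that("log-decline fitting recovers noiseless parameters exactly", {
  yrs <- c(2004, 2006, 2009, 2011)
  means <- 5 - 0.4 * log(yrs - 2004 + 1)
  tr <- fit_log_decline(stats::setNames(means, yrs), t0 = 2004)
  expect_equal(tr$a, 5, tolerance = 1e-6)
  expect_equal(tr$b, 0.4, tolerance = 1e-6)
  expect_false(tr$constant_flag)
})

test_that("flat series fit to zero slope; single years are rejected", {
  tr <- fit_log_decline(stats::setNames(rep(4.2, 4),
                                        c(2004, 2006, 2009, 2011)))
  expect_equal(tr$b, 0, tolerance = 1e-9)
  expect_error(fit_log_decline(stats::setNames(4.2, 2011)),
               "two distinct years")
  expect_error(fit_log_decline(stats::setNames(-1, c(2011))), "positive")
})

test_that("megacity provinces stay at their latest estimated level", {
  tr <- fit_log_decline(stats::setNames(c(5.0, 4.6), c(2004, 2011)),
                        megacity = TRUE)
  expect_true(tr$constant_flag)
  expect_equal(tr$b, 0)
  expect_equal(trend_value(tr, 2030), 4.6)
  expect_equal(project_intake(4.6, 2030, tr), project_intake(4.6, 2010, tr))
})

test_that("intake projection is monotone, clamped and horizon-checked", {
  tr <- fit_log_decline(stats::setNames(c(5.0, 4.2), c(2004, 2011)))
  expect_gt(tr$b, 0)
  p10 <- project_intake(5, 2010, tr)
  p30 <- project_intake(5, 2030, tr)
  expect_lte(p30, p10)
  # flat trend: constant intake
  tr0 <- fit_log_decline(stats::setNames(c(4, 4), c(2004, 2011)))
  expect_equal(project_intake(4, 2030, tr0), project_intake(4, 2010, tr0))
  # strong decline on a low consumer hits the floor
  trd <- list(a = 10, b = 4, constant_flag = FALSE, t0 = 2004)
  class(trd) <- "trend_params"
  expect_equal(project_intake(0.7, 2030, trd), 0.6)
  expect_error(project_intake(4, 2035, tr), "horizon")
})

test_that("risk-free threshold draws follow the PERT distribution", {
  spec <- tmrel_spec()
  set.seed(8)
  x <- draw_tmrel(1e5, spec)
  expect_true(all(x >= 0.6 & x <= 2.0))
  # closed-form PERT mean (0.6 + 4 * 1.5 + 2.0) / 6
  expect_lt(abs(mean(x) - 1.433333), 0.005)
  expect_error(tmrel_spec(1.5, 1.5, 1.5), "min < mode < max")
})

test_that("excess classification is a strict threshold", {
  expect_true(classify_excess(3.0, 1.5))
  expect_false(classify_excess(1.5, 1.5))
  expect_false(classify_excess(0.9, 1.2))
  expect_error(classify_excess(-1, 1.5), "positive")
  # exceedance under threshold uncertainty is monotone in intake
  set.seed(1)
  tm <- draw_tmrel(2000)
  p <- vapply(c(0.8, 1.2, 1.6, 2.2), function(i) mean(i > tm), numeric(1))
  expect_true(all(diff(p) >= 0))
})
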