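test_that("census margins form the full province x sex x age-band cross", {
  w <- small_world()
  census <- w$census
  expect_equal(nrow(census), 12 * 2 * 19)
  key <- paste(census$province, census$sex, census$age_band)
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(census$count >= 0))
  expect_true(all(census$region %in% c("north", "central", "south")))
  # region grouping: three north, three central, six south provinces
  reg <- unique(census[, c("province", "region")])
  expect_equal(as.integer(table(reg$region)[c("north", "central", "south")]),
               c(3L, 3L, 6L))
})

test_that("generated inputs are deterministic under a fixed seed", {
  cfg <- generator_config(recall_persons_per_wave = 50L)
  c1 <- generate_census(cfg, seed = 5)
  c2 <- generate_census(cfg, seed = 5)
  expect_identical(c1, c2)
  fct <- generate_fct()
  r1 <- generate_recalls(c1, fct, cfg, seed = 9)
  r2 <- generate_recalls(c1, fct, cfg, seed = 9)
  expect_identical(r1, r2)
  r3 <- generate_recalls(c1, fct, cfg, seed = 10)
  expect_false(identical(r1$recalls$amount_g, r3$recalls$amount_g))
})

test_that("a province mapped to an undefined region is rejected by name", {
  prov <- default_provinces <- saltsim:::default_provinces()
  prov$region[prov$province == "Hunan"] <- "west"
  expect_error(generator_config(provinces = prov), "Hunan")
})

test_that("zero within-person day variance gives identical recall days", {
  cfg <- generator_config(recall_persons_per_wave = 40L, sigma_within = 0)
  census <- generate_census(cfg, seed = 3)
  fct <- generate_fct()
  rec <- generate_recalls(census, fct, cfg, seed = 3)
  sodium <- rec$recalls$amount_g *
    fct$sodium_mg_per_100g[match(rec$recalls$food_code, fct$food_code)] / 1e5
  day_tot <- tapply(sodium, paste(rec$recalls$person_id,
                                  rec$recalls$day_index), sum)
  per_person <- tapply(as.numeric(day_tot),
                       sub(" [0-9]+$", "", names(day_tot)),
                       function(x) diff(range(x)))
  expect_lt(max(per_person), 1e-9)
})

test_that("pooled direct-addition sodium share matches the 67% target", {
  w <- small_world()
  sodium <- w$recalls$amount_g *
    w$fct$sodium_mg_per_100g[match(w$recalls$food_code,
                                   w$fct$food_code)] / 1e5
  cat <- w$fct$source_category[match(w$recalls$food_code, w$fct$food_code)]
  share <- sum(sodium[cat == "added_salt"]) / sum(sodium)
  expect_lt(abs(share - 0.67), 0.02)
})

test_that("source shares sum to one for every person-day", {
  w <- small_world()
  share_cols <- paste0("share_", saltsim:::SOURCE_CATEGORIES)
  sums <- rowSums(w$usual[, share_cols])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("megacity intake is flat across waves while others decline", {
  w <- small_world()
  by_pw <- aggregate(usual_sodium_g ~ province + survey_year, w$usual, mean)
  drift <- function(p) {
    sub <- by_pw[by_pw$province == p, ]
    sub$usual_sodium_g[sub$survey_year == 2011] -
      sub$usual_sodium_g[sub$survey_year == 2004]
  }
  # megacity: no systematic change beyond Monte-Carlo error (about
  # 2 SE of a between-wave mean difference at this wave size)
  expect_lt(abs(drift("Shanghai")), 0.9)
  # steepest declining province falls by roughly b * log(8)
  expect_lt(drift("Shandong"), -0.2)
})

test_that("rate tables satisfy their structural invariants", {
  w <- small_world()
  r <- w$rates
  expect_true(all(r$all_cause_mortality >= 0 & r$all_cause_mortality <= 1))
  expect_true(all(r$gca_mortality >= 0 & r$gca_mortality <= 1))
  expect_true(all(r$gca_prevalence >= 0 & r$gca_prevalence <= 1))
  expect_true(all(r$disability_weight >= 0 & r$disability_weight <= 1))
  # cancer rates strictly below all-cause mortality in every stratum
  expect_true(all(r$gca_mortality < r$all_cause_mortality))
  # age-increasing mortality
  for (s in c("female", "male")) {
    sub <- r[r$sex == s, ]
    ord <- match(saltsim:::AGE_BAND_LABELS, sub$age_band)
    expect_true(all(diff(sub$all_cause_mortality[ord]) > 0))
    expect_true(all(diff(sub$life_expectancy[ord]) < 0))
  }
  expect_gt(r$all_cause_mortality[r$sex == "male" & r$age_band == "80-84"],
            r$all_cause_mortality[r$sex == "male" & r$age_band == "30-34"])
  expect_error(validate_rate_tables(transform(r, gca_prevalence = -0.1)))
})

test_that("zero annual percent change leaves rates constant over years", {
  expect_equal(extrapolate_rate(0.01, 0, 15), 0.01)
  r <- generate_rate_tables(apc_mortality = 0)
  expect_equal(extrapolate_rate(r$all_cause_mortality, r$apc_mortality, 10),
               r$all_cause_mortality)
})

test_that("round-trip: usual-intake estimation recovers generator means", {
  # one province, adults only via age multipliers set to 1
  prov <- data.frame(province = "Uni", region = "north", megacity = TRUE,
                     base_mean_g = 4.0, decline_b = 0, pop_weight = 1)
  cfg <- generator_config(provinces = prov,
                          sex_mult = c(female = 1, male = 1),
                          age_mult = rep(1, 19),
                          recall_persons_per_wave = 1000L,
                          survey_years = 2011L, seed = 99L)
  census <- generate_census(cfg)
  fct <- generate_fct()
  rec <- generate_recalls(census, fct, cfg)
  usual <- estimate_usual_intake(rec$recalls, fct, rec$persons)
  # with equal recall days the mean of the shrunk intakes equals the
  # mean of the person means, whose SE is sd(person means)/sqrt(n)
  se <- stats::sd(usual$person_mean_g) / sqrt(nrow(usual))
  expect_lt(abs(mean(usual$usual_sodium_g) - 4.0), 2 * se + 0.02)
})

test_that("model input files are byte-identical across same-seed runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- generator_config(recall_persons_per_wave = 30L)
  write_model_inputs(cfg, d1, seed = 123)
  write_model_inputs(cfg, d2, seed = 123)
  for (f in c("census.csv", "fct.csv", "recalls.csv", "rates.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generator configuration survives a YAML round trip", {
  d <- withr::local_tempdir()
  cfg <- generator_config(recall_persons_per_wave = 25L, seed = 7L)
  write_generator_config(cfg, file.path(d, "cfg.yaml"))
  cfg2 <- read_generator_config(file.path(d, "cfg.yaml"))
  expect_equal(cfg2$provinces$base_mean_g, cfg$provinces$base_mean_g)
  expect_equal(cfg2$source_shares, cfg$source_shares)
  expect_equal(cfg2$seed, cfg$seed)
})
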