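# Synthetic-data generator: census margins, food-composition table,
# 24-h recall records, and rate tables with the statistical structure
# the downstream analysis assumes.

# Default province set: three northern, three central and six southern
# provinces; Beijing, Chongqing and Shanghai are megacities whose sodium
# exposure is held at its most recent survey level.  base_mean_g is the
# arithmetic-mean daily sodium intake (g/day) at the 2011 survey wave;
# decline_b is the log-decline slope (g/day per log-year since 2004).
default_provinces <- function() {
  data.frame(
    province = c("Beijing", "Heilongjiang", "Liaoning",
                 "Henan", "Jiangsu", "Shandong",
                 "Chongqing", "Hunan", "Hubei", "Guizhou", "Guangxi",
                 "Shanghai"),
    region = c("north", "north", "north",
               "central", "central", "central",
               "south", "south", "south", "south", "south", "south"),
    megacity = c(TRUE, FALSE, FALSE,
                 FALSE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    base_mean_g = c(4.9, 5.1, 5.0,
                    5.6, 5.3, 5.8,
                    4.5, 4.6, 4.7, 4.4, 4.3, 4.2),
    decline_b = c(0, 0.30, 0.28,
                  0.32, 0.30, 0.35,
                  0, 0.25, 0.26, 0.24, 0.22, 0),
    pop_weight = c(0.9, 1.7, 2.0,
                   4.3, 3.6, 4.4,
                   1.3, 3.0, 2.6, 1.6, 2.1, 1.1),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the input generator: the province table (region,
#' megacity flag, 2011 mean intake and log-decline slope), sex and age
#' intake multipliers, the between-person and within-person (day-to-day)
#' log-scale standard deviations, the target decomposition of sodium by
#' food source (direct addition dominating at 67%), and the survey design.
#'
#' @param provinces Data frame with columns `province`, `region`
#'   (north/central/south), `megacity` (logical), `base_mean_g` (mean daily
#'   sodium, g/day, at the last survey wave), `decline_b` (log-decline
#'   slope, g/day per log-year) and `pop_weight` (relative population size).
#' @param sex_mult Named multipliers on mean intake for `female` and `male`.
#' @param age_mult Multipliers on mean intake per age band (length 19).
#' @param sigma_between Between-person SD of log daily sodium.
#' @param sigma_within Within-person day-to-day SD of log daily sodium.
#' @param source_shares Named target shares of total sodium by source
#'   category; must sum to 1 and include all six categories.
#' @param share_concentration Dirichlet concentration controlling how much
#'   person-level shares scatter around the targets.
#' @param survey_years Integer survey wave years.
#' @param recall_persons_per_wave Persons sampled per survey wave.
#' @param scale Total census population across provinces (persons).
#' @param seed Default root seed used when operations are not given one.
#' @return An object of class `gen_config`.
#' @export
generator_config <- function(provinces = default_provinces(),
                             sex_mult = c(female = 0.92, male = 1.08),
                             age_mult = NULL,
                             sigma_between = 0.25,
                             sigma_within = 0.35,
                             source_shares = c(added_salt = 0.67,
                                               soy_sauce = 0.12,
                                               msg = 0.05,
                                               fermented = 0.045,
                                               pickled = 0.045,
                                               other = 0.07),
                             share_concentration = 80,
                             survey_years = c(2004L, 2006L, 2009L, 2011L),
                             recall_persons_per_wave = 500L,
                             scale = 200000,
                             seed = 20100101L) {
  if (is.null(age_mult)) {
    age_mult <- c(0.15, 0.30, 0.50, 0.70, 0.85, 0.95, 1.00, 1.05, 1.08,
                  1.10, 1.10, 1.10, 1.08, 1.00, 0.95, 0.90, 0.85, 0.80, 0.75)
  }
  stopifnot(nrow(provinces) >= 1,
            all(c("province", "region", "megacity", "base_mean_g",
                  "decline_b") %in% names(provinces)),
            length(age_mult) == length(AGE_BAND_LABELS),
            sigma_between > 0 || sigma_within >= 0)
  bad <- !provinces$region %in% REGIONS
  if (any(bad)) {
    stop("unknown region '", provinces$region[bad][1], "' for province ",
         provinces$province[bad][1],
         " (regions must be one of north, central, south)")
  }
  if (!setequal(names(source_shares), SOURCE_CATEGORIES)) {
    stop("source_shares must name exactly the six source categories")
  }
  if (abs(sum(source_shares) - 1) > 1e-8) {
    stop("source_shares must sum to 1")
  }
  if (sigma_within < 0 || sigma_between <= 0) {
    stop("log-scale SDs must be positive (within-person SD may be 0)")
  }
  if (is.null(provinces$pop_weight)) provinces$pop_weight <- 1
  names(age_mult) <- AGE_BAND_LABELS
  structure(list(provinces = provinces,
                 sex_mult = sex_mult,
                 age_mult = age_mult,
                 sigma_between = sigma_between,
                 sigma_within = sigma_within,
                 source_shares = source_shares[SOURCE_CATEGORIES],
                 share_concentration = share_concentration,
                 survey_years = as.integer(survey_years),
                 recall_persons_per_wave = as.integer(recall_persons_per_wave),
                 scale = scale,
                 seed = as.integer(seed)),
            class = "gen_config")
}

# Province mean daily sodium (g/day) at calendar year t: megacities are
# flat at their 2011 level, other provinces follow a - b*log(t - 2004 + 1)
# anchored so the curve passes through base_mean_g at the last survey wave.
province_mean_at <- function(config, province, year) {
  p <- config$provinces
  i <- match(province, p$province)
  if (any(is.na(i))) stop("unknown province: ", province[is.na(i)][1])
  t0 <- min(config$survey_years)
  t1 <- max(config$survey_years)
  a <- p$base_mean_g[i] + p$decline_b[i] * log(t1 - t0 + 1)
  ifelse(p$megacity[i], p$base_mean_g[i],
         pmax(a - p$decline_b[i] * log(year - t0 + 1), 0.8))
}

# China-2010-like age pyramid weights over the 19 census bands.
census_band_weights <- function() {
  w <- c(0.015, 0.045, 0.055, 0.060, 0.080, 0.095, 0.080, 0.075, 0.080,
         0.090, 0.075, 0.060, 0.055, 0.045, 0.033, 0.025, 0.017, 0.009,
         0.006)
  names(w) <- AGE_BAND_LABELS
  w
}

#' Generate synthetic census margins
#'
#' Produces the full cross of province x sex x age band with nonnegative
#' person counts following a realistic age pyramid, scaled by each
#' province's relative population weight.  Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to the config's census substream.
#' @return Data frame with columns `province`, `region`, `sex`, `age_band`,
#'   `count`.
#' @export
generate_census <- function(config = generator_config(),
                            seed = stream_seed(config$seed, "census")) {
  stopifnot(inherits(config, "gen_config"))
  p <- config$provinces
  bad <- !p$region %in% REGIONS
  if (any(bad)) {
    stop("unknown region '", p$region[bad][1], "' for province ",
         p$province[bad][1])
  }
  grid <- expand.grid(age_band = AGE_BAND_LABELS, sex = SEXES,
                      province = p$province, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$region <- p$region[match(grid$province, p$province)]
  w <- census_band_weights()[grid$age_band]
  pw <- p$pop_weight[match(grid$province, p$province)]
  expected <- config$scale * (pw / sum(p$pop_weight)) * w * 0.5
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid$count <- stats::rpois(nrow(grid), expected)
  grid[, c("province", "region", "sex", "age_band", "count")]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generate a toy food-composition table
#'
#' A fixed 30-item table (five foods per source category) giving sodium
#' content in mg per 100 g.  Direct-addition entries are salt-like
#' (roughly 39.3% sodium by weight); the "other" category carries the
#' low-sodium staple foods.
#'
#' @return Data frame with columns `food_code`, `sodium_mg_per_100g`,
#'   `source_category`.
#' @export
generate_fct <- function() {
  data.frame(
    food_code = sprintf("F%02d", 1:30),
    sodium_mg_per_100g = c(
      39340, 39100, 38800, 39000, 38600,   # added salt / salt blends
      6000, 6400, 5800, 6800, 5500,        # soy sauces
      12500, 12000, 13000, 12200, 12800,   # MSG / flavourings
      3000, 4500, 2600, 5200, 3800,        # fermented products
      2200, 3100, 1800, 2700, 1500,        # pickled vegetables
      450, 300, 600, 520, 380),            # other foods
    source_category = rep(SOURCE_CATEGORIES, each = 5),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic 24-hour recall records
#'
#' For each survey wave, samples persons from the census margins, draws a
#' person-level mean log sodium from their stratum (province x sex x age
#' band at that wave's province mean), then three consecutive recall days
#' lognormally around the person mean.  Each day's sodium is decomposed
#' into the six source categories with person-level Dirichlet shares
#' centred on the configured targets, and converted to food amounts via
#' the food-composition table.
#'
#' @param census Census margins from [generate_census()].
#' @param fct Food-composition table from [generate_fct()].
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to the config's recall substream.
#' @return List with `recalls` (person_id, survey_year, day_index,
#'   food_code, amount_g) and `persons` (person_id, survey_year, province,
#'   region, sex, age_band, age).
#' @export
generate_recalls <- function(census, fct, config = generator_config(),
                             seed = stream_seed(config$seed, "recalls")) {
  stopifnot(inherits(config, "gen_config"), nrow(fct) >= 1)
  missing_prov <- setdiff(census$province, config$provinces$province)
  if (length(missing_prov)) {
    stop("census stratum not covered by generator config: province ",
         missing_prov[1])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n_wave <- config$recall_persons_per_wave
  cell_prob <- census$count / sum(census$count)
  shares0 <- config$source_shares
  conc <- config$share_concentration
  # one representative food per category per person, sampled once
  foods_by_cat <- split(seq_len(nrow(fct)), fct$source_category)

  persons_list <- list()
  recalls_list <- list()
  for (yr in config$survey_years) {
    idx <- sample.int(nrow(census), n_wave, replace = TRUE, prob = cell_prob)
    band_i <- match(census$age_band[idx], AGE_BAND_LABELS)
    lo <- AGE_BAND_BREAKS[band_i]
    hi <- c(AGE_BAND_BREAKS[-1], 95)[band_i]
    age <- lo + floor(stats::runif(n_wave) * (hi - lo))
    pers <- data.frame(
      person_id = sprintf("P%d_%04d", yr, seq_len(n_wave)),
      survey_year = yr,
      province = census$province[idx],
      region = census$region[idx],
      sex = census$sex[idx],
      age_band = census$age_band[idx],
      age = age,
      stringsAsFactors = FALSE
    )
    m <- province_mean_at(config, pers$province, yr) *
      config$sex_mult[pers$sex] * config$age_mult[pers$age_band]
    sb <- config$sigma_between
    sw <- config$sigma_within
    mu_person <- log(m) - (sb^2 + sw^2) / 2 + stats::rnorm(n_wave, 0, sb)
    # person-level Dirichlet source shares centred on the targets
    g <- matrix(stats::rgamma(n_wave * 6, shape = rep(shares0 * conc,
                                                      each = n_wave)),
                nrow = n_wave)
    person_shares <- g / rowSums(g)
    colnames(person_shares) <- SOURCE_CATEGORIES
    food_pick <- vapply(SOURCE_CATEGORIES, function(cat) {
      pool <- foods_by_cat[[cat]]
      pool[sample.int(length(pool), n_wave, replace = TRUE)]
    }, integer(n_wave))

    day_mu <- rep(mu_person, each = 3)
    day_sodium <- exp(day_mu + stats::rnorm(3 * n_wave, 0, sw))
    # expand person x day x category
    pi_idx <- rep(seq_len(n_wave), each = 3)
    rec <- data.frame(
      person_id = rep(pers$person_id[pi_idx], each = 6),
      survey_year = yr,
      day_index = rep(rep(1:3, n_wave), each = 6),
      cat = rep(SOURCE_CATEGORIES, times = 3 * n_wave),
      stringsAsFactors = FALSE
    )
    cat_col <- match(rec$cat, SOURCE_CATEGORIES)
    person_row <- rep(pi_idx, each = 6)
    sodium_g_cat <- rep(day_sodium, each = 6) *
      person_shares[cbind(person_row, cat_col)]
    food_row <- food_pick[cbind(person_row, cat_col)]
    rec$food_code <- fct$food_code[food_row]
    rec$amount_g <- sodium_g_cat * 1000 * 100 / fct$sodium_mg_per_100g[food_row]
    rec$cat <- NULL
    persons_list[[as.character(yr)]] <- pers
    recalls_list[[as.character(yr)]] <- rec
  }
  list(recalls = do.call(rbind, recalls_list),
       persons = do.call(rbind, persons_list))
}

#' Generate synthetic rate tables
#'
#' All-cause mortality, population-level gastric-cancer mortality and
#' prevalence by sex and age band (age-increasing, cancer rates strictly
#' below all-cause mortality), annual percent changes for extrapolation,
#' a single unstratified disability weight, the linear excess-risk slope
#' per gram of sodium above the risk-free threshold, and residual life
#' expectancy decreasing in age.
#'
#' @param config A [generator_config()] (reserved for future stratum
#'   coupling; current tables are sex x age band).
#' @param disability_weight Disability weight for the gastric-cancer state.
#' @param rr_per_gram Excess-risk slope (RR increase per g/day above TMREL).
#' @param apc_mortality,apc_prevalence Annual percent changes (%/yr) used
#'   to extrapolate the 2010 rates forward.
#' @return Data frame of class `rate_tables`; one row per sex x age band
#'   with columns `all_cause_mortality`, `gca_mortality`, `gca_prevalence`,
#'   `apc_mortality`, `apc_prevalence`, `disability_weight`, `rr_per_gram`,
#'   `life_expectancy`.
#' @export
generate_rate_tables <- function(config = generator_config(),
                                 disability_weight = 0.28,
                                 rr_per_gram = 0.20,
                                 apc_mortality = -1.8,
                                 apc_prevalence = -0.5) {
  mid <- band_midpoints()
  grid <- expand.grid(age_band = AGE_BAND_LABELS, sex = SEXES,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  m <- mid[match(grid$age_band, AGE_BAND_LABELS)]
  sex_m <- ifelse(grid$sex == "male", 1.15, 0.90)
  sex_g <- ifelse(grid$sex == "male", 1.40, 0.75)
  grid$all_cause_mortality <- clamp01(0.0003 * exp(0.070 * m) * sex_m)
  grid$gca_prevalence <- clamp01(6e-5 * exp(0.060 * m) * sex_g)
  grid$gca_mortality <- clamp01(0.25 * grid$gca_prevalence)
  grid$apc_mortality <- apc_mortality
  grid$apc_prevalence <- apc_prevalence
  grid$disability_weight <- disability_weight
  grid$rr_per_gram <- rr_per_gram
  le0 <- ifelse(grid$sex == "male", 74.5, 79.0)
  grid$life_expectancy <- pmax(le0 - 0.80 * m, 1.5)
  out <- grid[, c("sex", "age_band", "all_cause_mortality", "gca_mortality",
                  "gca_prevalence", "apc_mortality", "apc_prevalence",
                  "disability_weight", "rr_per_gram", "life_expectancy")]
  class(out) <- c("rate_tables", "data.frame")
  validate_rate_tables(out)
  out
}

#' Validate a rate table
#'
#' Checks the structural invariants: probabilities and the disability
#' weight in \[0, 1\], nonnegative risk slope, and life expectancy
#' decreasing in age within sex.
#'
#' @param rates A rate table data frame.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_rate_tables <- function(rates) {
  probs <- c(rates$all_cause_mortality, rates$gca_mortality,
             rates$gca_prevalence)
  if (any(probs < 0 | probs > 1)) stop("rate probabilities must lie in [0,1]")
  if (any(rates$disability_weight < 0 | rates$disability_weight > 1)) {
    stop("disability_weight must lie in [0,1]")
  }
  if (any(rates$rr_per_gram < 0)) stop("rr_per_gram must be nonnegative")
  for (s in unique(rates$sex)) {
    sub <- rates[rates$sex == s, ]
    ord <- order(match(sub$age_band, AGE_BAND_LABELS))
    le <- sub$life_expectancy[ord]
    if (any(diff(le) >= 0)) {
      stop("life_expectancy must decrease with age within sex ", s)
    }
  }
  invisible(rates)
}

#' Write all synthetic model inputs to a directory
#'
#' Emits `census.csv`, `fct.csv`, `recalls.csv`, `persons.csv`,
#' `rates.csv` and the generator configuration as `config.yaml`
#' (UTF-8, header row, "." decimal separator).  Byte-identical for a
#' fixed seed.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if missing).
#' @param seed Root seed; substreams are derived per file.
#' @return Invisibly, a named list of the generated tables.
#' @export
write_model_inputs <- function(config = generator_config(), dir,
                               seed = config$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  census <- generate_census(config, seed = stream_seed(seed, "census"))
  fct <- generate_fct()
  rec <- generate_recalls(census, fct, config,
                          seed = stream_seed(seed, "recalls"))
  rates <- generate_rate_tables(config)
  utils::write.csv(census, file.path(dir, "census.csv"), row.names = FALSE)
  utils::write.csv(fct, file.path(dir, "fct.csv"), row.names = FALSE)
  utils::write.csv(rec$recalls, file.path(dir, "recalls.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(rates), file.path(dir, "rates.csv"),
                   row.names = FALSE)
  write_generator_config(config, file.path(dir, "config.yaml"))
  invisible(list(census = census, fct = fct, recalls = rec$recalls,
                 persons = rec$persons, rates = rates))
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path File path for the YAML document.
#' @return `write_generator_config()` returns the path invisibly;
#'   `read_generator_config()` returns a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$provinces <- as.list(as.data.frame(x$provinces))
  # named atomic vectors lose their names in YAML sequences; emit maps
  for (nm in c("sex_mult", "age_mult", "source_shares")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  generator_config(
    provinces = as.data.frame(x$provinces, stringsAsFactors = FALSE),
    sex_mult = unlist(x$sex_mult),
    age_mult = unlist(x$age_mult),
    sigma_between = x$sigma_between,
    sigma_within = x$sigma_within,
    source_shares = unlist(x$source_shares),
    share_concentration = x$share_concentration,
    survey_years = x$survey_years,
    recall_persons_per_wave = x$recall_persons_per_wave,
    scale = x$scale,
    seed = x$seed
  )
}
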