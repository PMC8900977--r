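# Disease progression: the annual loop of five actions (update risk
# factors, update excess status, update gastric-cancer status with an
# exposure lag, apply deaths, apply interventions), producing an event
# log from which all burden measures are computed.

#' Disease-model configuration
#'
#' @param lag_mean_years Mean delay (years) between excess sodium
#'   exposure and its effect on gastric-cancer incidence (default 8).
#' @param lag_distribution `"fixed"` (every individual uses exposure at
#'   year - 8) or `"poisson"` (individual lags drawn Poisson with the
#'   given mean).
#' @param horizon Simulated calendar years (closed cohort).
#' @param intake_floor Lower clamp on projected intake (g/day).
#' @param annual_noise_sd Optional SD of lognormal year-on-year individual
#'   intake noise beyond the trend (default 0 = none).
#' @return A list of class `disease_config`.
#' @export
disease_config <- function(lag_mean_years = 8,
                           lag_distribution = c("fixed", "poisson"),
                           horizon = c(2010L, 2030L),
                           intake_floor = 0.6,
                           annual_noise_sd = 0) {
  lag_distribution <- match.arg(lag_distribution)
  if (lag_mean_years <= 0) stop("lag_mean_years must be positive")
  if (horizon[1] >= horizon[2]) stop("horizon start must precede end")
  structure(list(lag_mean_years = lag_mean_years,
                 lag_distribution = lag_distribution,
                 horizon = as.integer(horizon),
                 intake_floor = intake_floor,
                 annual_noise_sd = annual_noise_sd),
            class = "disease_config")
}

#' Linear excess-risk relative risk
#'
#' `RR = 1 + rr_per_gram * max(0, intake - tmrel)`: risk rises linearly
#' with sodium above the risk-free threshold and equals 1 at or below it.
#'
#' @param intake_g Daily sodium intake (g/day).
#' @param tmrel_g Risk-free threshold (g/day).
#' @param rr_per_gram Slope (RR increase per g/day of excess), >= 0.
#' @return Relative risk >= 1.
#' @export
relative_risk <- function(intake_g, tmrel_g, rr_per_gram) {
  if (any(rr_per_gram < 0)) stop("rr_per_gram must be nonnegative")
  if (any(intake_g < 0) || any(tmrel_g < 0)) {
    stop("intake and threshold must be nonnegative")
  }
  1 + rr_per_gram * pmax(0, intake_g - tmrel_g)
}

#' Extrapolate a rate by its annual percent change
#'
#' `rate * (1 + apc/100)^years`, clamped to \[0, 1\].
#'
#' @param base_rate Annual probability in \[0, 1\].
#' @param apc Annual percent change (%/yr), signed.
#' @param years_elapsed Years since the base year.
#' @return Extrapolated probability.
#' @export
extrapolate_rate <- function(base_rate, apc, years_elapsed) {
  if (any(base_rate < 0 | base_rate > 1)) stop("base_rate must be in [0,1]")
  clamp01(base_rate * (1 + apc / 100)^years_elapsed)
}

#' Derive gastric-cancer incidence from prevalence and mortality
#'
#' One-compartment balance under no remission: at the observed prevalence
#' `P`, inflow `inc * (1 - P)` offsets outflow `P * (acm + cf)` where the
#' case-fatality hazard is the population-scale cancer mortality divided
#' by prevalence (capped).  Returns the annual incidence probability for
#' disease-free individuals.
#'
#' @param prev Prevalence proportion.
#' @param gca_mort Population-scale gastric-cancer mortality (per year).
#' @param acm All-cause mortality (per year).
#' @return Annual incidence probability in \[0, 1\].
#' @export
derive_incidence <- function(prev, gca_mort, acm) {
  cf <- ifelse(prev > 0, pmin(gca_mort / prev, 0.9), 0)
  clamp01(prev * (acm + cf) / pmax(1 - prev, 1e-9))
}

# Fast lookup environment over the rate table: one value per
# sex x age-band stratum, indexed on demand and extrapolated by APC.
build_rate_lookup <- function(rates) {
  key <- paste(rates$sex, rates$age_band)
  if (anyDuplicated(key)) stop("duplicate sex x age_band rows in rate table")
  has_inc <- "gca_incidence" %in% names(rates)
  prev <- rates$gca_prevalence
  cf <- ifelse(prev > 0, pmin(rates$gca_mortality / prev, 0.9), 0)
  inc0 <- if (has_inc) rates$gca_incidence else
    derive_incidence(prev, rates$gca_mortality, rates$all_cause_mortality)
  list(key = key,
       acm = rates$all_cause_mortality,
       prev = prev,
       case_fatality = cf,
       incidence = inc0,
       apc_m = rates$apc_mortality,
       apc_p = rates$apc_prevalence,
       le = rates$life_expectancy,
       dw = rates$disability_weight[1],
       rr_per_gram = rates$rr_per_gram[1])
}

rate_at <- function(lk, what, sex, age_band, years_elapsed) {
  i <- match(paste(sex, age_band), lk$key)
  if (anyNA(i)) {
    j <- which(is.na(i))[1]
    stop("rate table has no stratum for sex=", sex[j],
         " age_band=", age_band[j])
  }
  switch(what,
         all_cause_mortality = extrapolate_rate(lk$acm[i], lk$apc_m[i],
                                                years_elapsed),
         gca_prevalence = extrapolate_rate(lk$prev[i], lk$apc_p[i],
                                           years_elapsed),
         gca_incidence = extrapolate_rate(lk$incidence[i], lk$apc_p[i],
                                          years_elapsed),
         case_fatality = lk$case_fatality[i],
         life_expectancy = lk$le[i],
         stop("unknown rate: ", what))
}

#' Advance the population by one simulated year
#'
#' Applies the year's actions to every living individual: reclassifies
#' sodium-excess status from the supplied intake, draws incident gastric
#' cancer for never-diseased individuals with probability
#' `base_incidence * RR(lagged excess)`, and draws deaths binomially from
#' the stratum all-cause mortality, with gastric-cancer patients
#' additionally facing the case-fatality hazard.  Dead individuals never
#' change again.
#'
#' @param population A `population` data frame (see [build_population()]).
#' @param rates Rate table.
#' @param config A [disease_config()].
#' @param year Calendar year being simulated.
#' @param intake_g Current intake per individual (g/day); defaults to the
#'   population's usual intake.
#' @param intake_lagged Exposure driving this year's incidence (intake at
#'   year minus the lag); defaults to `intake_g`.
#' @param excess_multiplier Scales the lagged excess (intake - TMREL)
#'   before entering the relative risk; 1 is the factual world, 0 the
#'   everyone-at-TMREL counterfactual.
#' @param draws Optional list of uniform vectors `u_inc`, `u_death_ac`,
#'   `u_death_gca` (length n) enabling common-random-number coupling
#'   across scenarios; fresh draws are taken when omitted.
#' @return List with the updated `population` and the year's event-`log`
#'   rows (person_id, year, age, province, region, sex, state, intake_g,
#'   excess, incident_gca, died, cause).
#' @export
advance_year <- function(population, rates, config = disease_config(), year,
                         intake_g = population$usual_sodium_g,
                         intake_lagged = intake_g,
                         excess_multiplier = 1,
                         draws = NULL) {
  if (year < config$horizon[1] || year > config$horizon[2]) {
    stop("year ", year, " outside simulation horizon")
  }
  n <- nrow(population)
  if (n == 0) {
    return(list(population = population, log = empty_event_log()))
  }
  lk <- if (is.environment(rates) || is.list(rates) && !is.data.frame(rates))
    rates else build_rate_lookup(rates)
  if (is.null(draws)) {
    draws <- list(u_inc = stats::runif(n), u_death_ac = stats::runif(n),
                  u_death_gca = stats::runif(n))
  }
  alive <- population$state != "dead"
  band <- age_to_band(population$age)
  t_el <- year - config$horizon[1]

  excess <- alive & (intake_g > population$tmrel_g)
  lag_excess <- excess_multiplier * pmax(0, intake_lagged -
                                           population$tmrel_g)

  at_risk <- alive & population$state != "gca" & is.na(population$year_of_gca)
  p_inc <- rep(0, n)
  if (any(at_risk)) {
    base_inc <- rate_at(lk, "gca_incidence", population$sex[at_risk],
                        band[at_risk], t_el)
    rr <- 1 + lk$rr_per_gram * lag_excess[at_risk]
    p_inc[at_risk] <- clamp01(base_inc * rr)
  }
  incident <- at_risk & draws$u_inc < p_inc

  state <- population$state
  reclass <- alive & !incident & population$state != "gca"
  state[reclass] <- ifelse(excess[reclass], "sodium_excess", "healthy")
  state[incident] <- "gca"

  p_ac <- rep(0, n)
  p_ac[alive] <- rate_at(lk, "all_cause_mortality", population$sex[alive],
                         band[alive], t_el)
  d_ac <- alive & draws$u_death_ac < p_ac
  in_gca <- alive & state == "gca"
  p_cf <- rep(0, n)
  if (any(in_gca)) {
    p_cf[in_gca] <- rate_at(lk, "case_fatality", population$sex[in_gca],
                            band[in_gca], 0)
  }
  d_gca <- in_gca & draws$u_death_gca < p_cf
  died <- alive & (d_ac | d_gca)
  cause <- ifelse(died, ifelse(d_gca, "gca", "all_cause"), NA_character_)

  log <- data.frame(
    person_id = population$id[alive],
    year = year,
    age = population$age[alive],
    province = population$province[alive],
    region = population$region[alive],
    sex = population$sex[alive],
    state = state[alive],
    intake_g = intake_g[alive],
    excess = excess[alive],
    incident_gca = incident[alive],
    died = died[alive],
    cause = cause[alive],
    stringsAsFactors = FALSE
  )

  population$year_of_gca[incident] <- as.integer(year)
  population$state <- ifelse(died, "dead", ifelse(alive, state,
                                                  population$state))
  population$age <- population$age + as.integer(alive & !died)
  list(population = population, log = log)
}

empty_event_log <- function() {
  data.frame(person_id = character(), year = integer(), age = integer(),
             province = character(), region = character(), sex = character(),
             state = character(), intake_g = numeric(), excess = logical(),
             incident_gca = logical(), died = logical(), cause = character(),
             stringsAsFactors = FALSE)
}

#' Run the microsimulation over the full horizon
#'
#' Simulates every individual year by year under a scenario, with all
#' randomness pre-drawn from one seed in a scenario-independent order so
#' that scenarios run on common random numbers: rerunning with a
#' different intervention but the same seed couples every incidence and
#' death draw, which is what makes scenario contrasts (averted burden)
#' nearly noise-free.
#'
#' Each year, in order: the intervention transforms the individual's
#' sodium sources (from its start year, for individuals drawn into
#' uptake), the total intake for the year is formed from the projected
#' province trend plus the person offset, excess status is reclassified,
#' incident gastric cancer is drawn using the exposure of `lag` years
#' earlier (pre-2010 exposure back-filled from the fitted trend), and
#' deaths are drawn.  The exposure lag means an intervention starting in
#' 2010 first moves incidence in 2018.
#'
#' @param population A `population` (see [build_population()]).
#' @param rates Rate table.
#' @param trends Province trend table from [fit_province_trends()].
#' @param scenario A [scenario_spec()].
#' @param config A [disease_config()].
#' @param seed Integer seed for the whole run.
#' @param excess_multiplier Scales lagged excess before the relative
#'   risk; 0 gives the everyone-at-TMREL counterfactual used for
#'   attribution, intermediate values support dose-linearity checks.
#' @return An event log (class `event_log`): one row per person-year
#'   alive, with attributes `n` (cohort size), `seed` and `scenario`.
#' @export
simulate_cohort <- function(population, rates, trends,
                            scenario = scenario_spec("none"),
                            config = disease_config(), seed = 1,
                            excess_multiplier = 1) {
  stopifnot(inherits(scenario, "scenario_spec"))
  n <- nrow(population)
  years <- seq(config$horizon[1], config$horizon[2])
  if (n == 0) {
    out <- empty_event_log()
    class(out) <- c("event_log", "data.frame")
    attr(out, "n") <- 0L
    return(out)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  TT <- length(years)
  u_inc <- matrix(stats::runif(n * TT), n, TT)
  u_dac <- matrix(stats::runif(n * TT), n, TT)
  u_dgc <- matrix(stats::runif(n * TT), n, TT)
  u_uptake <- stats::runif(n)
  lag_i <- if (config$lag_distribution == "poisson") {
    pmax(1, stats::rpois(n, config$lag_mean_years))
  } else rep(round(config$lag_mean_years), n)
  noise <- if (config$annual_noise_sd > 0) {
    matrix(exp(stats::rnorm(n * TT, -config$annual_noise_sd^2 / 2,
                            config$annual_noise_sd)), n, TT)
  } else NULL

  base_year <- attr(population, "base_year", exact = TRUE) %||% config$horizon[1]
  ti <- trend_row(trends, population$province)
  # before the trend anchor year the log time-scale is undefined;
  # exposure there is held at the anchor-year level
  s_at <- function(yr) {
    ifelse(trends$constant_flag[ti], trends$a[ti],
           trends$a[ti] -
             trends$b[ti] * log(pmax(yr - trends$t0[ti] + 1, 1)))
  }
  offset <- population$usual_sodium_g - s_at(base_year)

  # intake history, back-filled pre-horizon from the trend (no
  # intervention exists before the simulation starts)
  max_lag <- max(lag_i)
  hist_years <- seq(config$horizon[1] - max_lag, config$horizon[2])
  hist <- matrix(NA_real_, n, length(hist_years),
                 dimnames = list(NULL, as.character(hist_years)))
  for (yr in hist_years[hist_years < config$horizon[1]]) {
    hist[, as.character(yr)] <- pmax(config$intake_floor, offset + s_at(yr))
  }

  share_cols <- paste0("share_", SOURCE_CATEGORIES)
  shares <- as.matrix(population[, share_cols])
  colnames(shares) <- SOURCE_CATEGORIES

  pop <- population
  lk <- build_rate_lookup(rates)
  logs <- vector("list", TT)
  for (t in seq_len(TT)) {
    yr <- years[t]
    base_total <- pmax(config$intake_floor, offset + s_at(yr))
    if (!is.null(noise)) {
      base_total <- pmax(config$intake_floor, base_total * noise[, t])
    }
    sources <- shares * base_total
    sources <- apply_scenario(sources, scenario, yr, uptake_draw = u_uptake)
    total <- pmax(rowSums(sources), 1e-9)
    hist[, as.character(yr)] <- total
    lag_yr <- pmax(yr - lag_i, hist_years[1])
    lagged <- hist[cbind(seq_len(n), match(lag_yr, hist_years))]
    step <- advance_year(pop, lk, config, yr,
                         intake_g = total, intake_lagged = lagged,
                         excess_multiplier = excess_multiplier,
                         draws = list(u_inc = u_inc[, t],
                                      u_death_ac = u_dac[, t],
                                      u_death_gca = u_dgc[, t]))
    pop <- step$population
    logs[[t]] <- step$log
  }
  out <- do.call(rbind, logs)
  class(out) <- c("event_log", "data.frame")
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "scenario") <- scenario_id(scenario)
  attr(out, "base_year") <- config$horizon[1]
  out
}
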