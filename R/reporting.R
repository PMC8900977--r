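# Summary quantities: percent reductions in cumulative burden, burden
# shares, equity ratios, validation relative errors and stratified
# breakdowns, plus the scenario-comparison driver that produces them.

#' Percent reduction in cumulative burden
#'
#' `100 * averted / baseline`, reported to two decimals (half-up), as in
#' the intervention dose-response tables where each percent is printed
#' with its numerator and denominator.
#'
#' @param averted Averted burden (same units as baseline), >= 0.
#' @param baseline Baseline burden, > 0.
#' @return Percent, rounded to 2 decimals.
#' @export
percent_reduction <- function(averted, baseline) {
  if (any(baseline <= 0)) stop("baseline burden must be positive")
  if (any(averted < 0)) stop("averted burden must be nonnegative")
  round_half_up(100 * averted / baseline, 2)
}

#' Share of a burden component in a total
#'
#' `100 * component / total` percent.
#'
#' @param component Component burden, >= 0.
#' @param total Total burden, > 0.
#' @return Percent (unrounded).
#' @export
burden_share <- function(component, total) {
  if (any(total <= 0)) stop("total burden must be positive")
  100 * component / total
}

#' Pairwise equity ratios of per-capita burden between regions
#'
#' @param per_capita_by_region Named positive numeric vector of
#'   per-capita (or per-1000) burdens by region.
#' @return Data frame of all ordered region pairs with their ratio.
#' @export
equity_ratio <- function(per_capita_by_region) {
  if (any(per_capita_by_region <= 0)) {
    stop("per-capita burdens must be positive for ratios")
  }
  rg <- names(per_capita_by_region)
  if (is.null(rg)) stop("regions must be named")
  pairs <- expand.grid(num = rg, den = rg, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$num != pairs$den, ]
  pairs$ratio <- per_capita_by_region[pairs$num] /
    per_capita_by_region[pairs$den]
  rownames(pairs) <- paste0(pairs$num, "/", pairs$den)
  pairs
}

#' Signed relative error of a model value against a reference
#'
#' `100 * (model - reference) / reference` percent, signed.
#'
#' @param model_value Model estimate.
#' @param reference_value Nonzero reference (e.g. literature) value.
#' @return Signed percent error.
#' @export
relative_error <- function(model_value, reference_value) {
  if (any(reference_value == 0)) stop("reference value must be nonzero")
  100 * (model_value - reference_value) / reference_value
}

#' Validate model values against user-supplied references
#'
#' @param modeled Named numeric vector of model estimates.
#' @param references Named numeric vector of reference values covering
#'   the same names.
#' @return Data frame with model, reference and signed relative error (%).
#' @export
validate_against <- function(modeled, references) {
  nm <- intersect(names(modeled), names(references))
  if (!length(nm)) stop("no common quantities between model and references")
  data.frame(quantity = nm,
             model = as.numeric(modeled[nm]),
             reference = as.numeric(references[nm]),
             relative_error_pct = relative_error(as.numeric(modeled[nm]),
                                                 as.numeric(references[nm])),
             stringsAsFactors = FALSE)
}

#' Run and compare intervention scenarios under common random numbers
#'
#' Simulates the no-intervention world, the everyone-at-TMREL
#' counterfactual and each requested scenario from the same population
#' and seed, computes cumulative discounted DALYs for each, and
#' assembles the reduction table: for every scenario the averted burden
#' (baseline minus scenario DALYs), the baseline attributable burden
#' (baseline minus counterfactual) as the denominator, and their percent
#' ratio — the numerator/denominator/percent triple the dose-response
#' tables print.
#'
#' @param population A `population`.
#' @param rates Rate table.
#' @param trends Province trends.
#' @param scenarios List of [scenario_spec()] (the `none` scenario and
#'   counterfactual are always run and need not be listed).
#' @param config A [disease_config()].
#' @param burden_cfg A [burden_config()].
#' @param seed Integer seed shared by every run (common random numbers).
#' @return An object of class `scenario_comparison`: the event logs, the
#'   per-scenario [compute_daly()] results, the baseline attributable
#'   burden and the reduction table.
#' @export
compare_scenarios <- function(population, rates, trends, scenarios = list(),
                              config = disease_config(),
                              burden_cfg = burden_config(), seed = 1) {
  log_none <- simulate_cohort(population, rates, trends,
                              scenario_spec("none"), config, seed)
  log_cf <- simulate_cohort(population, rates, trends,
                            scenario_spec("none"), config, seed,
                            excess_multiplier = 0)
  burden_none <- compute_daly(log_none, rates, burden_cfg)
  burden_cf <- compute_daly(log_cf, rates, burden_cfg)
  attributable <- burden_none$daly - burden_cf$daly
  n <- burden_none$n

  logs <- list(none = log_none, counterfactual = log_cf)
  burdens <- list(none = burden_none, counterfactual = burden_cf)
  rows <- list()
  for (sc in scenarios) {
    id <- scenario_id(sc)
    lg <- simulate_cohort(population, rates, trends, sc, config, seed)
    bd <- compute_daly(lg, rates, burden_cfg)
    logs[[id]] <- lg
    burdens[[id]] <- bd
    averted <- burden_none$daly - bd$daly
    rows[[id]] <- data.frame(
      scenario = id,
      averted_daly_per_1000 = 1000 * averted / n,
      baseline_daly_per_1000 = 1000 * attributable / n,
      percent = percent_reduction(max(averted, 0),
                                  max(attributable, 1e-12)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(logs = logs, burdens = burdens,
                 attributable_daly = attributable,
                 attributable_daly_per_1000 = 1000 * attributable / n,
                 n = n,
                 reduction_table = if (length(rows)) do.call(rbind, rows)
                 else NULL,
                 rates = rates, burden_cfg = burden_cfg,
                 scenarios = scenarios, seed = seed),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("Scenario comparison (n = %d, seed = %d)\n", x$n, x$seed))
  cat(sprintf("  baseline attributable DALYs per 1000: %.2f\n",
              x$attributable_daly_per_1000))
  if (!is.null(x$reduction_table)) {
    print(x$reduction_table, row.names = FALSE)
  }
  invisible(x)
}

# age groups used in the stratified summaries; breaks at 40 and 60
age_group_of <- function(age) {
  cut(age, breaks = c(-1, 39, 59, Inf), labels = c("0-39", "40-59", "60+"))
}

#' Stratified intervention summary
#'
#' Per-stratum averted burden, baseline attributable burden, percent
#' reduction and per-1000 rates for one scenario of a comparison.
#' Stratifiers: sex, age group (0-39 / 40-59 / 60+, by age at the base
#' year), region or province.  Strata partition the cohort, so stratum
#' DALYs sum exactly to the totals.
#'
#' @param comparison A [compare_scenarios()] result.
#' @param by One of `"sex"`, `"age_group"`, `"region"`, `"province"`.
#' @param scenario Scenario id (default: first scenario in the table).
#' @return Data frame with one row per stratum.
#' @export
stratified_summary <- function(comparison, by = c("sex", "age_group",
                                                  "region", "province"),
                               scenario = NULL) {
  stopifnot(inherits(comparison, "scenario_comparison"))
  by <- match.arg(by)
  if (is.null(scenario)) {
    if (is.null(comparison$reduction_table)) stop("no scenarios were run")
    scenario <- comparison$reduction_table$scenario[1]
  }
  if (!scenario %in% names(comparison$logs)) {
    stop("unknown scenario id: ", scenario)
  }
  logs <- comparison$logs
  base_year <- attr(logs$none, "base_year", exact = TRUE) %||% 2010L

  strat_col <- function(log) {
    if (by == "age_group") {
      base_age <- log$age - (log$year - base_year)
      as.character(age_group_of(base_age))
    } else log[[by]]
  }
  daly_by <- function(log) {
    lab <- strat_col(log)
    lv <- sort(unique(lab))
    vapply(lv, function(v) {
      sub <- log[lab == v, ]
      compute_daly(sub, comparison$rates, comparison$burden_cfg)$daly
    }, numeric(1))
  }
  n_by <- function(log) {
    lab <- strat_col(log)
    first <- !duplicated(log$person_id)
    table(factor(lab[first]))
  }
  d_none <- daly_by(logs$none)
  d_cf <- daly_by(logs$counterfactual)
  d_sc <- daly_by(logs[[scenario]])
  lv <- sort(unique(c(names(d_none), names(d_cf), names(d_sc))))
  get0n <- function(x, v) if (v %in% names(x)) x[[v]] else 0
  ns <- n_by(logs$none)
  out <- do.call(rbind, lapply(lv, function(v) {
    base_attr <- get0n(d_none, v) - get0n(d_cf, v)
    averted <- get0n(d_none, v) - get0n(d_sc, v)
    nn <- if (v %in% names(ns)) as.integer(ns[[v]]) else 0L
    data.frame(stratum = v, n = nn,
               averted_daly = averted,
               baseline_attributable_daly = base_attr,
               averted_daly_per_1000 = if (nn > 0) 1000 * averted / nn else 0,
               baseline_daly_per_1000 = if (nn > 0) 1000 * base_attr / nn
               else 0,
               percent = if (base_attr > 0)
                 percent_reduction(max(averted, 0), base_attr) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(out, "scenario") <- scenario
  attr(out, "by") <- by
  out
}
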