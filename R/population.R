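# Build the synthetic individuals whose province/sex/age composition
# matches the census margins.

#' Build a synthetic population matched to census margins
#'
#' Allocates `n` individuals to province x sex x age-band cells by
#' multinomial sampling with probabilities proportional to the census
#' counts, assigns ages uniformly within band, and gives each individual
#' a usual sodium intake and source-share decomposition drawn from a
#' donor in the matching stratum of `usual_intakes` (falling back to
#' province x sex, then province, then the full pool when a cell has no
#' donor).  Initial health states are assigned at the start: gastric
#' cancer with the stratum prevalence, otherwise sodium-excess when the
#' usual intake exceeds the individual's risk-free threshold, otherwise
#' healthy.  Nobody starts dead.
#'
#' @param census Census margins (province, region, sex, age_band, count).
#' @param usual_intakes Data frame of donor intakes with columns
#'   `usual_sodium_g`, `share_<category>` for the six source categories,
#'   and (optionally) `province`, `sex`, `age_band` used for matching.
#' @param n Number of individuals (default 10000, the full run size).
#' @param seed Integer seed.
#' @param rates Optional rate table supplying initial gastric-cancer
#'   prevalence; when `NULL` everyone starts cancer-free.
#' @param tmrel_g Risk-free sodium threshold (g/day) applied to every
#'   individual; a single value per run since threshold uncertainty is a
#'   parameter-level quantity explored in the probabilistic sensitivity
#'   analysis.
#' @param base_year Calendar base year of the population (2010).
#' @return Data frame of class `population`: one row per individual with
#'   id, province, region, sex, age, age_band, usual_sodium_g, the six
#'   `share_*` columns, tmrel_g, state and year_of_gca.
#' @export
build_population <- function(census, usual_intakes, n = 10000, seed = 1,
                             rates = NULL, tmrel_g = 1.5, base_year = 2010) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be at least 1")
  if (is.null(census) || nrow(census) == 0 || sum(census$count) <= 0) {
    stop("census margins are empty")
  }
  share_cols <- paste0("share_", SOURCE_CATEGORIES)
  stopifnot(all(c("usual_sodium_g", share_cols) %in% names(usual_intakes)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  idx <- sample.int(nrow(census), n, replace = TRUE,
                    prob = census$count / sum(census$count))
  band_i <- match(census$age_band[idx], AGE_BAND_LABELS)
  lo <- AGE_BAND_BREAKS[band_i]
  hi <- c(AGE_BAND_BREAKS[-1], 95)[band_i]
  age <- lo + floor(stats::runif(n) * (hi - lo))

  pop <- data.frame(
    id = sprintf("I%05d", seq_len(n)),
    province = census$province[idx],
    region = census$region[idx],
    sex = census$sex[idx],
    age = as.integer(age),
    age_band = census$age_band[idx],
    stringsAsFactors = FALSE
  )

  # donor matching: narrowest nonempty pool wins
  has_strata <- all(c("province", "sex") %in% names(usual_intakes))
  donor_idx <- integer(n)
  if (has_strata && "age_band" %in% names(usual_intakes)) {
    key3_d <- paste(usual_intakes$province, usual_intakes$sex,
                    usual_intakes$age_band)
    key3_p <- paste(pop$province, pop$sex, pop$age_band)
  } else {
    key3_d <- key3_p <- NULL
  }
  key2_d <- if (has_strata) paste(usual_intakes$province, usual_intakes$sex)
  key2_p <- if (has_strata) paste(pop$province, pop$sex)
  key1_d <- if (has_strata) usual_intakes$province
  key1_p <- if (has_strata) pop$province
  pools3 <- if (!is.null(key3_d)) split(seq_len(nrow(usual_intakes)), key3_d)
  pools2 <- if (has_strata) split(seq_len(nrow(usual_intakes)), key2_d)
  pools1 <- if (has_strata) split(seq_len(nrow(usual_intakes)), key1_d)
  all_pool <- seq_len(nrow(usual_intakes))
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    pool <- NULL
    if (!is.null(pools3)) pool <- pools3[[key3_p[i]]]
    if (is.null(pool) && has_strata) pool <- pools2[[key2_p[i]]]
    if (is.null(pool) && has_strata) pool <- pools1[[key1_p[i]]]
    if (is.null(pool)) pool <- all_pool
    donor_idx[i] <- pool[floor(u[i] * length(pool)) + 1L]
  }
  pop$usual_sodium_g <- usual_intakes$usual_sodium_g[donor_idx]
  for (col in share_cols) pop[[col]] <- usual_intakes[[col]][donor_idx]
  pop$tmrel_g <- tmrel_g

  # initial states from prevalence, then exposure classification
  prev <- rep(0, n)
  if (!is.null(rates)) {
    lk <- build_rate_lookup(rates)
    prev <- rate_at(lk, "gca_prevalence", pop$sex, pop$age_band, 0)
  }
  u_state <- stats::runif(n)
  pop$state <- ifelse(u_state < prev, "gca",
                      ifelse(pop$usual_sodium_g > pop$tmrel_g,
                             "sodium_excess", "healthy"))
  pop$year_of_gca <- ifelse(pop$state == "gca", base_year - 1L, NA_integer_)
  attr(pop, "base_year") <- base_year
  class(pop) <- c("population", "data.frame")
  pop
}
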