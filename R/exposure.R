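# Usual-intake estimation from 24-h recalls, province intake trends,
# intake projection, and the risk-free threshold (TMREL).

#' Estimate usual daily sodium intake from recall records
#'
#' Computes each person-day's sodium as
#' `sum(amount_g * sodium_mg_per_100g / 100 / 1000)` grams via the
#' food-composition table, then removes within-person day-to-day
#' variation by shrinking each person's observed mean toward their
#' stratum mean:
#' `usual = stratum_mean + (person_mean - stratum_mean) * s2b / (s2b + s2w / k)`
#' where `k` is the person's number of recall days and the within- and
#' between-person variance components come from a one-way
#' analysis-of-variance decomposition of daily sodium with person as the
#' factor.  Source shares are aggregated per person by food source
#' category.
#'
#' @param recalls Recall records (person_id, survey_year, day_index,
#'   food_code, amount_g).
#' @param fct Food-composition table (food_code, sodium_mg_per_100g,
#'   source_category).
#' @param persons Optional person metadata (person_id, survey_year,
#'   province, region, sex, age_band); when present, variance components
#'   and stratum means are computed within survey_year x province x sex
#'   groups and the metadata is carried through to the output.
#' @return Data frame with one row per person: `usual_sodium_g`,
#'   `person_mean_g`, `n_days`, and `share_<category>` columns summing
#'   to 1.
#' @export
estimate_usual_intake <- function(recalls, fct, persons = NULL) {
  m <- match(recalls$food_code, fct$food_code)
  if (anyNA(m)) {
    stop("food code not found in food-composition table: ",
         recalls$food_code[which(is.na(m))[1]])
  }
  sodium_g <- recalls$amount_g * fct$sodium_mg_per_100g[m] / 100 / 1000
  cat <- fct$source_category[m]

  day_key <- paste(recalls$person_id, recalls$day_index)
  day_tot <- tapply(sodium_g, day_key, sum)
  day_person <- sub(" [0-9]+$", "", names(day_tot))
  day_tot <- as.numeric(day_tot)

  person_ids <- sort(unique(recalls$person_id))
  pi <- match(day_person, person_ids)
  k <- tabulate(pi, nbins = length(person_ids))
  person_mean <- as.numeric(tapply(day_tot,
                                   factor(pi, levels = seq_along(person_ids)),
                                   mean))

  # grouping for stratum means / variance components
  if (!is.null(persons)) {
    pm <- match(person_ids, persons$person_id)
    if (anyNA(pm)) stop("persons table missing ids present in recalls")
    grp <- paste(persons$survey_year[pm], persons$province[pm],
                 persons$sex[pm])
  } else {
    grp <- rep("all", length(person_ids))
  }

  usual <- numeric(length(person_ids))
  for (g in unique(grp)) {
    pg <- which(grp == g)
    dg <- which(grp[pi] == g)
    # within-person variance: pooled over persons with >= 2 days
    resid2 <- (day_tot[dg] - person_mean[pi[dg]])^2
    df_w <- sum(pmax(k[pg] - 1, 0))
    s2w <- if (df_w > 0) sum(resid2) / df_w else 0
    kbar <- mean(k[pg])
    s2b <- max(0, stats::var(person_mean[pg]) - s2w / kbar)
    if (length(pg) < 2) s2b <- 0
    sm <- mean(person_mean[pg])
    B <- if (s2w == 0) 1 else s2b / (s2b + s2w / k[pg])
    usual[pg] <- sm + B * (person_mean[pg] - sm)
  }
  usual <- pmax(usual, 1e-6)

  # per-person source shares
  pkey <- match(recalls$person_id, person_ids)
  shares <- matrix(0, length(person_ids), length(SOURCE_CATEGORIES),
                   dimnames = list(NULL, SOURCE_CATEGORIES))
  for (cc in SOURCE_CATEGORIES) {
    sel <- cat == cc
    if (any(sel)) {
      tot <- tapply(sodium_g[sel], factor(pkey[sel],
                                          levels = seq_along(person_ids)),
                    sum)
      shares[, cc] <- ifelse(is.na(tot), 0, as.numeric(tot))
    }
  }
  shares <- shares / pmax(rowSums(shares), 1e-12)

  out <- data.frame(person_id = person_ids,
                    usual_sodium_g = usual,
                    person_mean_g = person_mean,
                    n_days = k,
                    stringsAsFactors = FALSE)
  colnames(shares) <- paste0("share_", SOURCE_CATEGORIES)
  out <- cbind(out, as.data.frame(shares))
  if (!is.null(persons)) {
    pm <- match(out$person_id, persons$person_id)
    for (col in intersect(c("survey_year", "province", "region", "sex",
                            "age_band", "age"), names(persons))) {
      out[[col]] <- persons[[col]][pm]
    }
  }
  out
}

#' Fit a logarithmic decline to province mean intakes
#'
#' Least-squares fit of `S(t) = a - b * log(t - t0 + 1)` to yearly mean
#' intakes.  For megacity provinces no trend is fitted: the intake is
#' held constant at the most recent year's mean (`b = 0`,
#' `constant_flag = TRUE`).
#'
#' @param yearly_means Named numeric vector (names are calendar years) or
#'   a data frame with columns `year` and `mean_g`.
#' @param t0 Anchor year of the logarithmic time scale (first survey wave).
#' @param megacity Logical; hold intake constant at the latest level.
#' @param province Optional province label carried into the result.
#' @return A list of class `trend_params` with `a`, `b`, `constant_flag`,
#'   `t0` and `province`.
#' @export
fit_log_decline <- function(yearly_means, t0 = 2004, megacity = FALSE,
                            province = NA_character_) {
  if (is.data.frame(yearly_means)) {
    yrs <- yearly_means$year
    mns <- yearly_means$mean_g
  } else {
    yrs <- as.numeric(names(yearly_means))
    mns <- as.numeric(yearly_means)
  }
  if (any(mns <= 0)) stop("yearly means must be positive")
  if (megacity) {
    a <- mns[which.max(yrs)]
    tr <- list(a = a, b = 0, constant_flag = TRUE, t0 = t0,
               province = province)
    class(tr) <- "trend_params"
    return(tr)
  }
  if (length(unique(yrs)) < 2) {
    stop("at least two distinct years are needed to fit a decline",
         " for a non-megacity province")
  }
  x <- log(yrs - t0 + 1)
  fit <- stats::lm.fit(cbind(1, -x), mns)
  tr <- list(a = unname(fit$coefficients[1]),
             b = unname(fit$coefficients[2]),
             constant_flag = FALSE, t0 = t0, province = province)
  class(tr) <- "trend_params"
  tr
}

#' Evaluate a fitted trend at calendar years
#'
#' @param trend A `trend_params` object.
#' @param year Calendar year(s).
#' @return Province mean intake `S(year)` in g/day.
#' @export
trend_value <- function(trend, year) {
  if (trend$constant_flag) rep(trend$a, length(year))
  else trend$a - trend$b * log(year - trend$t0 + 1)
}

#' Fit intake trends for every province
#'
#' Aggregates usual intakes to province x survey-year means and fits
#' [fit_log_decline()] per province, honouring megacity flags.
#'
#' @param usual Output of [estimate_usual_intake()] including `province`
#'   and `survey_year` columns.
#' @param provinces Province table with `province` and `megacity` columns.
#' @param t0 Anchor year.
#' @return Data frame with columns `province`, `a`, `b`, `constant_flag`,
#'   `t0`.
#' @export
fit_province_trends <- function(usual, provinces, t0 = 2004) {
  res <- lapply(provinces$province, function(pv) {
    sub <- usual[usual$province == pv, ]
    if (nrow(sub) == 0) stop("no recall persons for province ", pv)
    mns <- tapply(sub$usual_sodium_g, sub$survey_year, mean)
    tr <- fit_log_decline(data.frame(year = as.numeric(names(mns)),
                                     mean_g = as.numeric(mns)),
                          t0 = t0,
                          megacity = provinces$megacity[provinces$province == pv],
                          province = pv)
    data.frame(province = pv, a = tr$a, b = tr$b,
               constant_flag = tr$constant_flag, t0 = t0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

trend_row <- function(trends, province) {
  i <- match(province, trends$province)
  if (anyNA(i)) stop("no trend fitted for province ", province[is.na(i)][1])
  i
}

# Vectorised S(year) over persons given the trends table.
trend_value_at <- function(trends, province, year) {
  i <- trend_row(trends, province)
  ifelse(trends$constant_flag[i], trends$a[i],
         trends$a[i] - trends$b[i] * log(year - trends$t0[i] + 1))
}

#' Project an individual's intake to a calendar year
#'
#' The individual's trajectory is the fitted province trend plus a
#' constant person offset (usual intake minus the province trend at the
#' base year), floored at `floor_g` so projections can never become
#' nonphysical.  Monotone non-increasing in year when the decline slope
#' is positive.
#'
#' @param usual_g Usual intake (g/day) at `base_year`.
#' @param year Target calendar year, within `horizon`.
#' @param trend A `trend_params` object (or one row of
#'   [fit_province_trends()] output coerced via `as_trend()`).
#' @param base_year Base year at which `usual_g` is anchored.
#' @param floor_g Lower clamp, default 0.6 g/day (the lower bound of the
#'   risk-free range).
#' @param horizon Allowed projection years.
#' @return Projected intake in g/day.
#' @export
project_intake <- function(usual_g, year, trend, base_year = 2010,
                           floor_g = 0.6, horizon = c(2010, 2030)) {
  if (any(year < horizon[1] | year > horizon[2])) {
    stop("projection year outside horizon [", horizon[1], ", ",
         horizon[2], "]")
  }
  offset <- usual_g - trend_value(trend, base_year)
  pmax(floor_g, offset + trend_value(trend, year))
}

#' Risk-free sodium threshold specification (PERT)
#'
#' The theoretical minimum-risk exposure level for sodium, modelled as a
#' PERT distribution on 0.6-2 g/day with mode 1.5 g/day.
#'
#' @param min_g,mode_g,max_g Range and mode in g/day.
#' @param shape PERT shape parameter (classic value 4).
#' @return A list of class `tmrel_spec`.
#' @export
tmrel_spec <- function(min_g = 0.6, mode_g = 1.5, max_g = 2.0, shape = 4) {
  if (!(min_g < mode_g && mode_g < max_g)) {
    stop("TMREL spec requires min < mode < max")
  }
  structure(list(min_g = min_g, mode_g = mode_g, max_g = max_g,
                 shape = shape), class = "tmrel_spec")
}

#' Draw risk-free thresholds from a PERT distribution
#'
#' PERT(a, m, b) is a Beta(1 + s(m-a)/(b-a), 1 + s(b-m)/(b-a)) rescaled
#' to \[a, b\]; its mean is (a + 4m + b)/6 for the classic shape s = 4.
#'
#' @param n Number of draws.
#' @param spec A [tmrel_spec()].
#' @return Numeric vector of draws in \[min_g, max_g\].
#' @export
draw_tmrel <- function(n = 1, spec = tmrel_spec()) {
  stopifnot(inherits(spec, "tmrel_spec"))
  rng <- spec$max_g - spec$min_g
  alpha <- 1 + spec$shape * (spec$mode_g - spec$min_g) / rng
  beta <- 1 + spec$shape * (spec$max_g - spec$mode_g) / rng
  spec$min_g + rng * stats::rbeta(n, alpha, beta)
}

#' Classify excess sodium status
#'
#' An individual is in the sodium-excess state exactly when intake is
#' strictly above the risk-free threshold; the boundary is not excess.
#'
#' @param intake_g Daily intake (g/day), positive.
#' @param tmrel_g Risk-free threshold (g/day), positive.
#' @return Logical vector.
#' @export
classify_excess <- function(intake_g, tmrel_g) {
  if (any(intake_g <= 0) || any(tmrel_g <= 0)) {
    stop("intake and threshold must be positive")
  }
  intake_g > tmrel_g
}
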