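# One-way deterministic sensitivity analysis and Monte-Carlo
# probabilistic sensitivity analysis (PSA) with percentile credible
# intervals.

#' One-way sensitivity analysis
#'
#' Reruns the model with each parameter in turn moved to
#' `(1 - delta) * baseline` and `(1 + delta) * baseline` (all other
#' parameters and the seed held fixed), recording the outcome at both
#' ends.  Parameters with declared bounds are clamped so probabilities
#' stay valid.  A failed rerun is recorded in the row's message, not
#' fatal.
#'
#' @param runner Function taking a named list of parameter values and
#'   returning a single numeric outcome.
#' @param baseline_params Named list of numeric scalar parameters.
#' @param delta Proportional perturbation (default 0.10).
#' @param bounds Optional named list of `c(lower, upper)` clamps per
#'   parameter.
#' @return Data frame: parameter, baseline outcome, low and high outcome,
#'   and any error messages.
#' @export
one_way <- function(runner, baseline_params, delta = 0.10, bounds = list()) {
  stopifnot(is.function(runner), length(baseline_params) >= 1)
  base_out <- runner(baseline_params)
  run1 <- function(params) {
    tryCatch(list(value = runner(params), error = NA_character_),
             error = function(e) list(value = NA_real_,
                                      error = conditionMessage(e)))
  }
  rows <- lapply(names(baseline_params), function(nm) {
    v <- baseline_params[[nm]]
    clamp <- function(x) {
      if (!is.null(bounds[[nm]])) {
        pmin(pmax(x, bounds[[nm]][1]), bounds[[nm]][2])
      } else x
    }
    lo_p <- baseline_params
    hi_p <- baseline_params
    lo_p[[nm]] <- clamp(v * (1 - delta))
    hi_p[[nm]] <- clamp(v * (1 + delta))
    lo <- run1(lo_p)
    hi <- run1(hi_p)
    data.frame(parameter = nm, baseline = base_out,
               low = lo$value, high = hi$value,
               error_low = lo$error, error_high = hi$error,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PSA specification
#'
#' @param n_runs Number of Monte-Carlo runs (default 10000, the full
#'   analysis size; scale down for quick checks).
#' @param params Named list of distribution specs, each a list with a
#'   `dist` element (`"fixed"`, `"normal"`, `"lognormal"`, `"beta"`,
#'   `"uniform"` or `"pert"`) and its parameters (`value`; `mean`, `sd`;
#'   `meanlog`, `sdlog`; `shape1`, `shape2`; `min`, `max`; `min`, `mode`,
#'   `max`).
#' @param interval_level Credible-interval level (default 0.95).
#' @param seed Root seed; per-run seeds are derived from it.
#' @return A list of class `psa_spec`.
#' @export
psa_spec <- function(n_runs = 10000L, params = list(),
                     interval_level = 0.95, seed = 1L) {
  if (n_runs < 1) stop("n_runs must be at least 1")
  if (interval_level <= 0 || interval_level >= 1) {
    stop("interval_level must lie in (0,1)")
  }
  for (nm in names(params)) .validate_dist(params[[nm]], nm)
  structure(list(n_runs = as.integer(n_runs), params = params,
                 interval_level = interval_level, seed = as.integer(seed)),
            class = "psa_spec")
}

.validate_dist <- function(d, nm) {
  if (!is.list(d) || is.null(d$dist)) {
    stop("invalid distribution spec for parameter ", nm)
  }
  need <- switch(d$dist,
                 fixed = "value", normal = c("mean", "sd"),
                 lognormal = c("meanlog", "sdlog"),
                 beta = c("shape1", "shape2"),
                 uniform = c("min", "max"),
                 pert = c("min", "mode", "max"),
                 stop("unknown distribution '", d$dist, "' for parameter ",
                      nm))
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("distribution for ", nm, " is missing: ",
         paste(missing, collapse = ", "))
  }
  invisible(d)
}

.draw_dist <- function(d, n) {
  switch(d$dist,
         fixed = rep(d$value, n),
         normal = stats::rnorm(n, d$mean, d$sd),
         lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
         beta = stats::rbeta(n, d$shape1, d$shape2),
         uniform = stats::runif(n, d$min, d$max),
         pert = draw_tmrel(n, tmrel_spec(d$min, d$mode, d$max)))
}

#' Probabilistic sensitivity analysis
#'
#' Draws every parameter independently from its distribution for each of
#' `n_runs` runs, evaluates the model once per run (with a per-run seed
#' derived deterministically from the root seed and the run index, so
#' results do not depend on execution order), and summarises each
#' outcome as its mean with equal-tailed percentile credible bounds.
#'
#' @param runner Function `(params, seed)` returning a named numeric
#'   vector of outcomes (a bare numeric works too).
#' @param spec A [psa_spec()].
#' @return A list of class `psa_result`: `draws` (run x outcome data
#'   frame including the parameter draws) and `estimates` (one row per
#'   outcome: point = mean of draws, lower, upper, level).
#' @export
psa <- function(runner, spec) {
  stopifnot(inherits(spec, "psa_spec"), is.function(runner))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_runs
  par_draws <- lapply(spec$params, .draw_dist, n = n)
  run_seeds <- (as.numeric(spec$seed) + 1009 * seq_len(n)) %% 2147483629

  out <- vector("list", n)
  for (i in seq_len(n)) {
    params <- lapply(par_draws, `[[`, i)
    val <- runner(params, as.integer(run_seeds[i]))
    if (is.null(names(val))) names(val) <- paste0("outcome",
                                                  seq_along(val))
    out[[i]] <- val
  }
  outcomes <- do.call(rbind, out)
  alpha <- (1 - spec$interval_level) / 2
  est <- do.call(rbind, lapply(colnames(outcomes), function(nm) {
    x <- outcomes[, nm]
    data.frame(outcome = nm, point = mean(x),
               lower = unname(stats::quantile(x, alpha)),
               upper = unname(stats::quantile(x, 1 - alpha)),
               level = spec$interval_level, stringsAsFactors = FALSE)
  }))
  draws <- cbind(data.frame(run = seq_len(n)),
                 as.data.frame(par_draws),
                 as.data.frame(outcomes))
  structure(list(draws = draws, estimates = est, spec = spec),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d runs, %.0f%% equal-tailed credible intervals\n",
              x$spec$n_runs, 100 * x$spec$interval_level))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
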