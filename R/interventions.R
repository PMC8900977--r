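# The two cooking-salt interventions, expressed as transformations of an
# individual's sodium source decomposition: salt-restriction spoons cap
# direct salt addition; low-sodium salt substitutes replace a fraction
# of the five high-sodium food categories with a 65% NaCl blend.

#' Define an intervention scenario
#'
#' @param kind `"none"`, `"spoon"` (salt-restriction spoon capping daily
#'   added-salt sodium) or `"substitute"` (low-sodium salt substitute
#'   replacing a fraction of the five high-sodium categories).
#' @param spoon_sodium_mg Daily added-salt sodium cap in mg (spoon only).
#'   The study doses 197/394/591/788 mg correspond to 1/4 to 1 of a 2-g
#'   salt spoon at 39.4% sodium; other positive values are allowed.
#' @param substitute_fraction Fraction of the five high-sodium categories
#'   replaced by the substitute, in \[0, 1\] (substitute only).
#' @param substitute_nacl_share NaCl share of the substitute blend
#'   (default 0.65: 65% NaCl, 25% KCl, 10% MgSO4).
#' @param start_year First calendar year the intervention applies.
#' @param uptake Proportion of individuals adopting the intervention.
#' @param spoon_mode `"cap"` (added-salt sodium capped at the spoon
#'   content; default) or `"subtract"` (reduced by that amount), the two
#'   readings of the spoon dose.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("none", "spoon", "substitute"),
                          spoon_sodium_mg = NULL,
                          substitute_fraction = NULL,
                          substitute_nacl_share = 0.65,
                          start_year = 2010L,
                          uptake = 1,
                          spoon_mode = c("cap", "subtract")) {
  kind <- match.arg(kind)
  spoon_mode <- match.arg(spoon_mode)
  if (uptake < 0 || uptake > 1) stop("uptake must lie in [0,1]")
  if (kind == "spoon") {
    if (is.null(spoon_sodium_mg) || spoon_sodium_mg < 0) {
      stop("spoon scenario needs a nonnegative spoon_sodium_mg")
    }
    if (!is.null(substitute_fraction)) {
      stop("spoon scenario must not set substitute_fraction")
    }
  } else if (kind == "substitute") {
    if (is.null(substitute_fraction) || substitute_fraction < 0 ||
        substitute_fraction > 1) {
      stop("substitute scenario needs substitute_fraction in [0,1]")
    }
    if (substitute_nacl_share < 0 || substitute_nacl_share > 1) {
      stop("substitute_nacl_share must lie in [0,1]")
    }
    if (!is.null(spoon_sodium_mg)) {
      stop("substitute scenario must not set spoon_sodium_mg")
    }
  } else {
    if (!is.null(spoon_sodium_mg) || !is.null(substitute_fraction)) {
      stop("scenario 'none' takes no intervention parameters")
    }
  }
  structure(list(kind = kind,
                 spoon_sodium_mg = spoon_sodium_mg,
                 substitute_fraction = substitute_fraction,
                 substitute_nacl_share = substitute_nacl_share,
                 start_year = as.integer(start_year),
                 uptake = uptake,
                 spoon_mode = spoon_mode),
            class = "scenario_spec")
}

#' Scenario identifier string
#'
#' @param scenario A [scenario_spec()].
#' @return A short id such as `"none"`, `"spoon_788"` or
#'   `"substitute_0.95"`, used to key all outputs.
#' @export
scenario_id <- function(scenario) {
  switch(scenario$kind,
         none = "none",
         spoon = paste0("spoon_", format(scenario$spoon_sodium_mg)),
         substitute = paste0("substitute_",
                             format(scenario$substitute_fraction)))
}

as_source_matrix <- function(sodium_by_source) {
  if (is.matrix(sodium_by_source)) {
    x <- sodium_by_source
  } else {
    x <- matrix(sodium_by_source, nrow = 1,
                dimnames = list(NULL, names(sodium_by_source)))
  }
  if (is.null(colnames(x))) stop("sodium sources must be named by category")
  unknown <- setdiff(colnames(x), SOURCE_CATEGORIES)
  if (length(unknown)) stop("unknown source category: ", unknown[1])
  x
}

#' Apply the salt-restriction spoon to a source decomposition
#'
#' Caps the added-salt sodium at the spoon's daily sodium content (in
#' `"cap"` mode) or reduces it by that amount (`"subtract"` mode); all
#' other categories are unchanged.
#'
#' @param sodium_by_source Named numeric vector or matrix (columns named
#'   by source category) of daily sodium in g/day.
#' @param spoon_sodium_mg Spoon sodium content in mg/day.
#' @param mode `"cap"` or `"subtract"`.
#' @return The transformed decomposition, same shape as the input.
#' @export
apply_spoon <- function(sodium_by_source, spoon_sodium_mg,
                        mode = c("cap", "subtract")) {
  mode <- match.arg(mode)
  if (spoon_sodium_mg < 0) stop("spoon sodium content must be nonnegative")
  x <- as_source_matrix(sodium_by_source)
  if (any(x < 0)) stop("sodium amounts must be nonnegative")
  if ("added_salt" %in% colnames(x)) {
    cap_g <- spoon_sodium_mg / 1000
    x[, "added_salt"] <- if (mode == "cap") pmin(x[, "added_salt"], cap_g)
    else pmax(x[, "added_salt"] - cap_g, 0)
  }
  if (is.matrix(sodium_by_source)) x else stats::setNames(drop(x),
                                                          colnames(x))
}

#' Apply the salt substitute to a source decomposition
#'
#' Replaces a `fraction` of each of the five high-sodium categories
#' (added salt, soy sauce, MSG, fermented, pickled) with the substitute
#' blend, leaving `(1 - fraction) + fraction * nacl_share` of the sodium;
#' the `other` category is unchanged.
#'
#' @param sodium_by_source Named numeric vector or matrix of daily sodium
#'   in g/day by category.
#' @param fraction Fraction replaced, in \[0, 1\].
#' @param nacl_share NaCl share of the blend, in \[0, 1\] (default 0.65).
#' @return The transformed decomposition, same shape as the input.
#' @export
apply_substitute <- function(sodium_by_source, fraction, nacl_share = 0.65) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0,1]")
  if (nacl_share < 0 || nacl_share > 1) stop("nacl_share must lie in [0,1]")
  x <- as_source_matrix(sodium_by_source)
  keep <- (1 - fraction) + fraction * nacl_share
  cols <- intersect(colnames(x), SUBSTITUTABLE_CATEGORIES)
  x[, cols] <- x[, cols] * keep
  if (is.matrix(sodium_by_source)) x else stats::setNames(drop(x),
                                                          colnames(x))
}

#' Apply a scenario to individual source decompositions
#'
#' Dispatches to the matching transformation for the individuals drawn
#' into uptake, from the scenario's start year onward; the `none`
#' scenario and years before the start are the identity.
#'
#' @param sources Matrix (individuals x categories) or named vector of
#'   daily sodium in g/day.
#' @param scenario A [scenario_spec()].
#' @param year Calendar year.
#' @param uptake_draw Optional uniform draw per individual deciding
#'   adoption (adopts when below `uptake`); with the default all
#'   individuals adopt iff `uptake` is 1.
#' @return The transformed sources, same shape as the input.
#' @export
apply_scenario <- function(sources, scenario, year, uptake_draw = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (scenario$kind == "none" || year < scenario$start_year ||
      scenario$uptake == 0) {
    return(sources)
  }
  x <- as_source_matrix(sources)
  sel <- if (is.null(uptake_draw)) {
    rep(scenario$uptake >= 1, nrow(x))
  } else uptake_draw < scenario$uptake
  if (any(sel)) {
    xt <- switch(scenario$kind,
                 spoon = apply_spoon(x[sel, , drop = FALSE],
                                     scenario$spoon_sodium_mg,
                                     scenario$spoon_mode),
                 substitute = apply_substitute(x[sel, , drop = FALSE],
                                               scenario$substitute_fraction,
                                               scenario$substitute_nacl_share))
    x[sel, ] <- xt
  }
  if (is.matrix(sources)) x else stats::setNames(drop(x), colnames(x))
}

#' Write / read a scenario as YAML
#'
#' @param scenario A [scenario_spec()].
#' @param path File path.
#' @return The path (write) or a [scenario_spec()] (read).
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(scenario)), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_spec(kind = x$kind,
                spoon_sodium_mg = x$spoon_sodium_mg,
                substitute_fraction = x$substitute_fraction,
                substitute_nacl_share = x$substitute_nacl_share %||% 0.65,
                start_year = x$start_year %||% 2010L,
                uptake = x$uptake %||% 1,
                spoon_mode = x$spoon_mode %||% "cap")
}
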