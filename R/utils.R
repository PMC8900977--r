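# Shared constants and small helpers.

# Census age bands: 0-1, 1-4, then 5-year increments up to 85+.
AGE_BAND_BREAKS <- c(0, 1, seq(5, 85, by = 5))
AGE_BAND_LABELS <- c("0-1", "1-4",
                     paste(seq(5, 80, 5), seq(9, 84, 5), sep = "-"),
                     "85+")

# Sodium source categories; the first five are the substitutable
# high-sodium foods, "other" is everything else.
SOURCE_CATEGORIES <- c("added_salt", "soy_sauce", "msg",
                       "fermented", "pickled", "other")
SUBSTITUTABLE_CATEGORIES <- SOURCE_CATEGORIES[1:5]

REGIONS <- c("north", "central", "south")
SEXES <- c("female", "male")

#' Map an age in years to its census age band
#'
#' @param age Integer vector of ages in completed years (>= 0).
#' @return Character vector of band labels ("0-1", "1-4", "5-9", ..., "85+").
#' @export
age_to_band <- function(age) {
  if (any(age < 0)) stop("ages must be nonnegative")
  AGE_BAND_LABELS[findInterval(age, AGE_BAND_BREAKS)]
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed through
#' named independent substreams (census, recalls, population,
#' simulation, ...) so each generated file and model stage is
#' reproducible on its own.  The derived seed stays below 2^31.
#'
#' @param seed Integer root seed.
#' @param stream Substream name.
#' @return An integer seed.
#' @export
stream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  offset <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + offset) %% 2147483629)
}

# Half-up rounding (round() in R is half-even); percents in the reported
# tables use 2-decimal half-up.
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Midpoint age of each band, used by the rate generator.
band_midpoints <- function() {
  c(0.5, 3, seq(7, 82, by = 5), 90)
}
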