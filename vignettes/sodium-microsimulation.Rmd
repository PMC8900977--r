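---
title: "Modelling dietary sodium and gastric cancer burden with saltsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dietary sodium and gastric cancer burden with saltsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltsim)
```

## The model

`saltsim` is a discrete-time stochastic microsimulation of the gastric
cancer (GCa) burden attributable to excess dietary sodium in a
multi-province population followed from 2010 to 2030.  Unlike a Markov
cohort model, it simulates named individuals, so the full distribution
of sodium intake — and its province, sex and age structure — propagates
into the distribution of outcomes.

Each simulated year applies five actions to every living individual:

1. **Update risk factors.** Age advances; daily sodium intake follows
   the individual's trajectory, a province-level trend plus a constant
   person offset.
2. **Update sodium-excess status.** An individual is in the
   *sodium-excess* state exactly when current intake exceeds their
   risk-free threshold (TMREL).
3. **Update GCa status.** Never-diseased individuals acquire GCa with
   probability `base_incidence × RR`, where
   `RR = 1 + rr_per_gram × max(0, intake_lagged − TMREL)` is a linear
   dose-response on *lagged* excess intake: the exposure that drives
   incidence in year *y* is the intake of year *y − 8* (the mean lag
   between exposure and cancer onset).  Only the first episode is
   modelled.
4. **Apply deaths.** Deaths are Bernoulli draws from the stratum
   all-cause mortality; individuals in the GCa state additionally face
   a case-fatality hazard.  Dead is absorbing.
5. **Apply interventions.** From the scenario's start year, the
   intervention transforms the individual's sodium source
   decomposition before the year's exposure is classified, so an
   intervention starting in 2010 first moves incidence in 2018 through
   the lag.

Health states are exactly one of healthy, sodium-excess, GCa and dead.
Burden is accounted in discounted disability-adjusted life years
(DALYs): years of life lost (YLL) sum, over GCa deaths, the
residual-life-expectancy stream with every future lost year discounted
back to the base year; years lived with disability (YLD) weight each
discounted person-year in the GCa state by a single unstratified
disability weight.  The default discount rate is 3 %/yr.

### Attribution by counterfactual simulation

The burden "due to excess sodium" is the difference in DALYs between
the factual world and a counterfactual in which everyone sits at their
risk-free threshold, both simulated from the same population and the
same random-number streams (common random numbers, CRN).  Internally
the counterfactual multiplies every lagged excess by 0
(`excess_multiplier = 0` in `simulate_cohort()`); intermediate
multipliers scale excess proportionally, which is also how the
dose-linearity of the model is verified in the test suite.  CRN makes
scenario contrasts nearly noise-free: an intervention can only ever
remove incident cases relative to the baseline run on the same seed,
never add them.

We deliberately do not use a population-attributable-fraction formula:
the microsimulation already produces both worlds, and a PAF would
double-count the lag structure.

## Exposure estimation

Usual daily sodium intake is estimated from short-term 24-h recalls in
three steps:

* **Composition matching.** Each recalled food amount is converted to
  sodium via the food-composition table:
  `sodium_g = amount_g × sodium_mg_per_100g / 100 / 1000`.
* **Within-person variance correction.** Person means over `k` recall
  days are shrunk toward the stratum mean with the classical factor
  `σ²_between / (σ²_between + σ²_within / k)`; variance components come
  from a one-way analysis-of-variance decomposition (person as factor)
  of daily sodium on the natural scale.  Working on the natural scale
  keeps the shrinkage identity exact — the usual intake always lies
  between the person mean and the stratum mean, the spread of usual
  intakes never exceeds the spread of person means, and the stratum
  mean is preserved — and avoids assuming the lognormal family that
  the synthetic generator happens to use.  The decomposition is
  deliberately modular and could be replaced by a log-scale or
  covariate-adjusted variant without touching the rest of the
  pipeline.
* **Source decomposition.** Sodium is aggregated per person into six
  source categories — added salt, soy sauce, MSG, fermented products,
  pickled foods, and other — whose shares sum to 1 and are carried
  through the simulation, because the interventions act on sources,
  not totals.

### Intake trends

Province mean intake follows a logarithmic decline
`S(t) = a − b·log(t − t0 + 1)` fitted by least squares to the survey
wave means (waves 2004, 2006, 2009, 2011; `t0 = 2004`).  Megacity
provinces, surveyed only from 2011, are held constant at their 2011
level through 2030.  An individual's trajectory is the province trend
plus the constant offset `usual − S(base year)`, which preserves
within-province rank order — important because the salt-restriction
spoon acts on the upper tail.  Projections are floored at 0.6 g/day
(the lower bound of the risk-free range), and years before `t0` reuse
the `t0` level when the 8-year lag reaches back past the survey era.

### The risk-free threshold

TMREL is PERT-distributed on 0.6–2.0 g/day with mode 1.5 g/day
(classic shape 4; the Beta reparameterisation with mean
`(min + 4·mode + max)/6 ≈ 1.433`).  One draw is shared by all
individuals within a probabilistic-sensitivity iteration: threshold
uncertainty is a parameter-level quantity, not individual
heterogeneity, so drawing it per person would understate its
contribution to outcome uncertainty.  Deterministic base-case runs use
the mode, 1.5 g/day.

## Interventions

Two culturally specific cooking-salt strategies are modelled as
transformations of the per-person source decomposition, applied
annually from the scenario start year to the individuals drawn into
uptake (default full compliance):

* **Salt-restriction spoon** — caps daily *added-salt* sodium at the
  spoon's content: 197, 394, 591 or 788 mg sodium, i.e. one quarter to
  one whole 2-g salt spoon at 39.4 % sodium.  The cap reading (rather
  than subtracting the spoon amount) matches the doses' description as
  spoon volumes used to control addition during cooking; the
  subtraction reading remains available via `spoon_mode = "subtract"`.
* **Salt substitute** — replaces a fraction *f* (0.65–0.95) of the five
  high-sodium categories with a blend of 65 % NaCl, 25 % KCl and 10 %
  MgSO₄, leaving `(1 − f) + 0.65·f` of their sodium; the "other"
  category is untouched.  Potassium-related health effects of the
  substitute are not modelled.

Both transformations are monotone — they never increase any category —
so under CRN the averted burden is ordered in the dose: increasing in
the substitution fraction, decreasing in the spoon size.

## Rates and the incidence balance

Rate tables are keyed by sex and age band (0–1, 1–4, then 5-year bands
to 85+) and extrapolated over calendar time by annual percent changes,
`rate × (1 + APC/100)^years`, clamped to [0, 1].  The tables carry
*population-scale* GCa mortality and prevalence (both strictly below
all-cause mortality).  The simulation needs two quantities the tables
do not state directly and derives both from a one-compartment,
remission-free balance:

* case fatality among prevalent cases, `cf = gca_mortality /
  prevalence` (capped at 0.9/yr);
* baseline incidence for disease-free individuals,
  `inc = prevalence × (acm + cf) / (1 − prevalence)`,
  the inflow that sustains the observed prevalence against its
  outflow.

A `gca_incidence` column in the rate table overrides the derivation,
which is how the test suite pins exact incidence probabilities for its
binomial oracles.

## The synthetic-data generator

No deposited survey, census or rate data exist for this problem, so
the package generates all inputs with the statistical structure the
analysis assumes; the generator is first-class, tested code, and its
defaults are the study conditions.

* **Census margins**: 12 provinces in three dietary regions — north
  (Beijing, Heilongjiang, Liaoning), central (Henan, Jiangsu,
  Shandong), south (Chongqing, Hunan, Hubei, Guizhou, Guangxi,
  Shanghai) — fully crossed with sex and the 19 age bands, with a
  China-2010-like age pyramid and province population weights.
* **Recalls**: per survey wave, persons are sampled from the census
  margins; person-level mean log intake is normal around the stratum
  mean (province trend × sex × age multipliers), and three consecutive
  recall days are lognormal around the person mean.  Defaults:
  between-person SD 0.25 and within-person SD 0.35 on the log scale —
  day-to-day variation in sodium exceeding between-person variation,
  as is typical for single nutrients; province means near 4.2–5.8
  g/day sodium in 2011 with the central region highest; log-decline
  slopes of 0.22–0.35 g per log-year in the nine declining provinces
  and flat megacities.  Source shares are person-level Dirichlet draws
  centred on a decomposition in which direct addition carries 67 % of
  sodium.
* **Food-composition table**: a fixed 30-item toy table, five foods
  per category, spanning salt-like (≈39 % sodium) to staple foods —
  the smallest set that exercises code matching and source
  decomposition.
* **Rate tables**: Gompertz-like age-increasing all-cause mortality,
  GCa prevalence rising to ≈0.7 % at the oldest ages with male
  predominance, population GCa mortality at one quarter of prevalence
  (a case fatality of ≈0.25/yr), mildly negative APCs, disability
  weight 0.28, risk slope 0.20 per g/day of excess, and residual life
  expectancy declining linearly in age.  These levels put the
  simulated cohort's GCa incidence near 30 per 100,000 person-years,
  a realistic magnitude for the setting.

All randomness flows from a single root seed through named substreams
(`stream_seed(seed, "census")`, `"recalls"`, `"population"`, ...), so
every generated file is reproducible on its own and a fixed root seed
yields byte-identical pipeline outputs.

What the generator does *not* emulate — and hence what passing tests
cannot show about real data: survey weighting and non-response,
urbanicity strata, realistic food nomenclature, correlation between
intake level and food choice, measurement error in recalls relative to
urinary sodium, and province-specific relative risks.  Absolute burden
numbers from synthetic inputs are not comparable to published national
estimates; the package's claims are structural (orderings, linearity,
conservation, calibration recovery), not numerical reproductions.

## Numerical choices

* Intake floor 0.6 g/day everywhere a projection or anchoring could
  otherwise go nonphysical.
* Excess is *strictly* above threshold; the boundary is not excess.
* The exposure lag is a fixed 8-year delay by default; an optional
  Poisson(8) individual lag (truncated at 1) is available in
  `disease_config()`.
* Event order within a year: intervention → intake update → excess
  classification → incidence → death, so an intervention feeds the
  same year's exposure but, through the lag, only later incidence.
* YLL discounts each future lost life-year to the base year (the
  annuity `(1 − v^⌊LE⌋)/(1 − v) + frac·v^⌊LE⌋` at the death year,
  times the death-year discount factor).  No age weights, no
  half-cycle correction.
* Reported percents are rounded half-up to two decimals; every percent
  is emitted together with its numerator and denominator so it can be
  recomputed.
* PSA intervals are equal-tailed empirical percentiles (not highest
  density), the standard presentation for probabilistic sensitivity
  analysis; per-run seeds derive deterministically from the root seed
  and run index, so results are independent of execution order.

## Problem sizes

Full analyses use 10,000 individuals and 10,000 PSA runs.  The test
suite and the bundled acceptance script run the same code on 2,000
individuals, 500 recall persons per wave and 200 PSA runs — sizes
chosen so the whole suite exercises every path in a few minutes while
keeping Monte-Carlo error small enough for the 2–3-standard-error
assertions it makes.  At 2,000 individuals a 21-year cohort yields
only a few dozen incident cancers, so single-seed scenario contrasts
are granular; the acceptance script therefore pools averted and
attributable DALYs over several coupled replicate seeds before forming
percents.

## Worked example

```{r example, eval = FALSE}
library(saltsim)

out <- tempfile("saltsim-")
res <- run_pipeline(out, n_population = 2000, seed = 1)
res$comparison
stratified_summary(res$comparison, by = "region",
                   scenario = "substitute_0.95")
```

## Known limitations

* One disease pathway: sodium affects mortality only through GCa;
  cardiovascular endpoints are out of scope.
* Closed cohort: no births or migration over 2010–2030.
* First-episode GCa only; no staging, treatment or recurrence.
* The generator's distributional families (lognormal intake, Dirichlet
  shares) are conveniences, not estimates; the within:between variance
  ratio is a knob, not data.
* Costs and cost-effectiveness are not modelled.
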