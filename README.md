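# saltsim

Microsimulation of excess dietary sodium and gastric cancer (GCa)
burden in a multi-province population, 2010–2030, with the two
China-specific cooking-salt interventions — salt-restriction spoons and
low-sodium salt substitutes — and full uncertainty analysis.

The package is aimed at health-economic and epidemiological modellers
who want an individual-level (not cohort-average) simulation of a
dietary risk factor: it builds a synthetic population matched to census
margins, estimates usual sodium intake from 24-h dietary recalls,
projects province intake trends, advances individuals through health
states year by year, and accounts burden in discounted
disability-adjusted life years (DALYs).

## The model in brief

Each individual carries a usual sodium intake (g/day), a decomposition
of that sodium over six food sources, and a risk-free threshold (TMREL)
drawn from PERT(0.6, 1.5, 2.0) g/day. Annually:

* intake follows the fitted province trend `S(t) = a − b·log(t − t0 + 1)`
  plus a constant person offset (megacities are held at their latest
  survey level);
* excess status is `intake > TMREL`;
* incident GCa strikes never-diseased individuals with probability
  `base_incidence × RR`, where `RR = 1 + β·max(0, intake(t−8) − TMREL)`
  is a linear dose-response on intake lagged by the 8-year mean
  exposure-to-onset delay;
* deaths are binomial on stratum all-cause mortality, plus a
  case-fatality hazard for GCa cases;
* interventions transform the sodium source decomposition (spoon: cap
  added-salt sodium at 197–788 mg/day; substitute: replace a fraction
  of the five high-sodium categories with a 65 % NaCl blend).

Burden: `DALY = YLL + YLD` at a 3 % annual discount; the burden *due to
excess sodium* is the DALY difference between the factual run and an
everyone-at-TMREL counterfactual executed on common random numbers, so
intervention contrasts are nearly noise-free. No real survey, census or
rate data are shipped: a tested synthetic-data generator produces every
input with the structure the analysis assumes (right-skewed
province/sex/age-specific intake with 67 % of sodium from direct
addition, declining 2004–2011 trends, age-increasing mortality and
cancer rates).

## Worked example

```r
library(saltsim)

out <- tempfile("saltsim-")
res <- run_pipeline(out, n_population = 2000, seed = 1)
res$comparison
```

```
Scenario comparison (n = 2000, seed = 61169)
  baseline attributable DALYs per 1000: 57.54
        scenario averted_daly_per_1000 baseline_daly_per_1000 percent
       spoon_788              12.46297               57.54188   21.66
 substitute_0.95              12.46297               57.54188   21.66
```

Reading: without intervention, excess sodium accounts for 57.5
discounted DALYs per 1000 individuals over 2010–2030 in this synthetic
cohort; capping added cooking salt at 788 mg sodium/day averts 12.5 of
them (21.66 %). At 2,000 individuals a 21-year cohort yields a few
dozen incident cancers, so single-seed contrasts are granular (here the
two interventions avert the same case set; they separate when pooled
over replicate seeds, as the acceptance script does). Stratified views:

```r
stratified_summary(res$comparison, by = "region", scenario = "substitute_0.95")
```

```
  stratum   n averted_daly baseline_attributable_daly averted_daly_per_1000 baseline_daly_per_1000 percent
1 central 842    19.649353                  88.592362             23.336523             105.216582   22.18
2   north 338     0.000000                  21.214806              0.000000              62.765700    0.00
3   south 820     5.276587                   5.276587              6.434863               6.434863  100.00
```

The central region — highest intake, largest population — carries the
largest attributable burden per 1000, matching the model's intake
gradient. `run_pipeline()` also writes every table as CSV (`table2.csv`
dose-response triples, `table3.csv` province × strategy, `burden.csv`,
`equity.csv`, `shares.csv`, event logs and all generated inputs), and a
fixed root seed makes the whole output directory byte-identical across
runs.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/saltsim.R generate --out inputs/ --seed 1
Rscript inst/cli/saltsim.R compare  --out results/ --n 2000 --seed 1
Rscript inst/cli/saltsim.R psa      --out psa.csv --runs 200 --seed 1
```

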