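Package: saltsim
Title: Microsimulation of Dietary Sodium Exposure and Gastric Cancer Burden
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time stochastic microsimulation of excess dietary
    sodium exposure and gastric cancer burden in a multi-province
    population. Builds a synthetic population matched to census margins,
    estimates usual sodium intake from 24-hour dietary recalls with a
    within-person variance correction, projects province-level intake
    trends on a logarithmic decline, advances individuals through
    healthy / sodium-excess / gastric-cancer / dead states with a lagged
    linear dose-response on excess intake above a PERT-distributed
    risk-free threshold, and accounts burden in discounted
    disability-adjusted life years. Includes two cooking-salt
    interventions (salt-restriction spoons and low-sodium salt
    substitutes), counterfactual attribution under common random
    numbers, one-way and probabilistic sensitivity analysis, and a
    synthetic-data generator so the whole pipeline runs without
    restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
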