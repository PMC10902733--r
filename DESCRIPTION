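Package: firearmMRP
Title: Household Firearm Ownership Estimation by Multilevel Regression
    and Poststratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of individuals living in households
    with a firearm (HFR) across US states, years, and demographic
    subgroups by multilevel regression and poststratification (MRP).
    A Bayesian additive regression tree (BART) probit model predicts
    household firearm ownership from state, year, gender, marital status,
    race and ethnicity, urbanicity, survey mode, and a smoothed estimate
    of the proportion of suicides committed with a firearm (FSS);
    posterior stratum-year probabilities are reweighted by stratum
    population shares to yield population estimates with credible
    intervals.  Includes a Kitagawa-style decomposition of HFR change
    into within-strata rate change and population-composition change, a
    variance partition of the estimate surface over demographic factors,
    a least-squares calibration of the FSS proxy with state and subgroup
    bias audits, and a synthetic survey-data generator with a known truth
    surface for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
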