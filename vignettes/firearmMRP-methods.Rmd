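---
title: "Estimating household firearm ownership by MRP: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating household firearm ownership by MRP: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

The quantity of interest is HFR: the proportion of individuals living in a
household with a firearm, resolved by state, year (1990--2018) and
demographics.  No single survey measures it with that resolution.  A small
in-person survey asks the question in 16 waves across the whole window; a
much larger telephone survey asks it in only three years (2001, 2002, 2004).
Most state-demographic cells therefore contain few or no respondents in most
years, and direct cell proportions are unusable.

`firearmMRP` follows the multilevel-regression-and-poststratification (MRP)
template:

1. fit a regularised model of the binary household-firearm response on
   respondent covariates;
2. predict the response probability on the full grid of analytic strata
   (state x gender x marital status x race/ethnicity x urbanicity) by year;
3. average the grid predictions with poststratification weights
   proportional to each stratum's adult population in the target year.

Step 1 uses Bayesian additive regression trees (BART) with a probit link,
so step 2 yields a full posterior over the stratum-year probability surface
and every downstream quantity (state estimates, subgroup estimates, change
decompositions) carries an equal-tailed credible interval obtained by
applying the same weighted average to each posterior draw.

### Analytic strata

Strata are the cross of state with four binary demographic factors.
States flagged in the packaged metadata as lacking a large densely
populated county contribute only `nonurban` strata; with seven such states
the frame has `43 * 16 + 7 * 8 = 744` strata.  The identity of the seven
flag-free states (AK, ME, MT, ND, SD, VT, WY) is a package fixture chosen
among low-population states: the *rule* (no large urban county) is the
contract, and the metadata CSV is editable.  The frame builder also accepts
a subset of states, which the test-suite fixtures use; ordering is always
lexicographic so frames are reproducible.

## The outcome model

The default engine is a probit BART written for this package (`src/bart.cpp`):

* sum of `m` trees, `f(x) = sum_j g(x; T_j, M_j)`;
* node-splitting prior `P(split at depth d) = alpha (1+d)^-beta`
  with the standard `alpha = 0.95`, `beta = 2`;
* leaf values `mu ~ N(0, sigma_mu^2)` with `sigma_mu = 3/(k sqrt(m))`,
  `k = 2`, so the ensemble's prior mass for `f` sits inside roughly
  `[-3, 3]` on the probit scale;
* binary outcomes via Albert--Chib latent variables
  `z ~ N(offset + f(x), 1)` truncated by the response, with
  `offset = qnorm(mean response)`;
* Metropolis--Hastings tree moves grow / prune / change with the leaf
  values integrated out in closed form (the residual variance is fixed at
  1 by the probit augmentation, so no variance sampling is needed).

Two implementation choices matter for scale and are worth stating:

* **Binomial cells, not expanded records.**  All respondents (or suicides)
  sharing a covariate vector form one cell with `trials` and `successes`.
  Trees can never separate records within a cell, so per-leaf likelihood
  contributions depend only on cell sums of the latent variables.  The
  per-cell latent sum is drawn exactly (record by record) for cells with at
  most 32 records and via a normal approximation to the sum of truncated
  normals above that -- the moments are exact and the CLT error at n > 32 is
  negligible relative to posterior spread.  This makes the sampler
  O(cells), so fit time does not grow with survey size or suicide counts.
* **Lazy prediction.**  `fit_hfr_model()` binds data to an engine;
  the MCMC runs when `predict_strata_probabilities()` first needs it,
  with training and grid prediction sharing one chain, and the posterior is
  cached on the fitted object.  Rerunning prediction with the same grid
  returns the identical cached array.

Covariates are year (continuous, letting trees pool adjacent years), the
50 state indicators, the four binary demographics, the survey indicator,
and smoothed FSS (below).  Predictions are made with the survey indicator
held at the in-person level -- the generator defines truth as the mode-free
probability, and the level is a configurable sensitivity knob
(`reference_survey`).

Default engine settings are a desk-scale preset (50 trees, 300 burn-in,
500 kept draws); `engine_settings("production")` raises this to 200/1000/1000.
The desk preset was sized so the full default synthetic study (below) fits
in about a minute and a half on one CPU.

### Fallback engine

`engine = "hierarchical"` fits a binomial logistic GLMM (`lme4::glmer`)
with the demographic main effects, the gender x marital interaction,
survey, scaled year and smoothed FSS as fixed effects and a state random
intercept.  Posterior draws are simulated from Gaussian approximations
around the fitted fixed effects (using their covariance) and the state
conditional modes (using their conditional variances).  It is fast and
deterministic, used for speed-sensitive pipelines and as a cross-check:
under a main-effects generator the two engines agree on national estimates
within three percentage points (tested).

## Smoothed FSS

The fraction of suicides by firearm (FSS) is the field's standard ownership
proxy, but most stratum-years have zero or very few suicides, leaving raw
FSS undefined or wildly variable.  A second BART (year, state, demographics;
no survey or FSS covariates) is fitted to the suicide counts as binomial
cells, and its posterior mean probability is the *smoothed FSS* for every
stratum-year, defined even where no suicides occurred and shrunk toward
similar strata where data are thin.  A `"logistic"` fallback (binomial GLM
with a natural year spline and factor main effects) is available for fast
tests.  The ownership model can also be run without the FSS covariate
(`include_fss = FALSE`), mirroring the published with/without variants.

Proxy *calibration*, by contrast, deliberately uses raw count-aggregated
FSS at state-year (and group-year) level, where counts are large enough for
the ratio to be stable -- that is the proxy practitioners actually use.

## Synthetic study and what it does (not) show

Restricted survey microdata, population models and death records cannot be
shipped, so the package carries a generator whose defaults *are* the study
conditions:

* truth surface: logistic in an intercept (-2.6), Gaussian state effects
  (sd 0.6), four demographic main effects (man +1.1, married +0.45,
  White/AIAN +1.0, nonurban +0.9), a gender x marital interaction (+0.75,
  lifting married women toward married men), and a linear year trend
  (-0.008/yr).  The implied national HFR is in the 0.44--0.50 range in 1990
  (the exact level depends on the seed's state-effect draw) and declines by
  roughly 0.09--0.10 to 2018, matching the scale of the published estimates;
* surveys: 16 in-person waves (1990--2018) of 1,400 and three telephone
  years (2001/02/04) of 5,000 -- 37,400 respondents at desk scale.  The
  full-scale preset reproduces the source surveys' sizes
  (22,430 + 691,028 = 713,458) and is used only for accounting checks;
* telephone responses get a +0.15 log-odds mode offset; the magnitude is a
  free parameter (no published value exists), and truth is the mode-free
  level;
* population: product-of-margins stratum shares with linear drift
  (+0.004/yr each toward unmarried, minority and urban), state totals
  log-normal around 100,000 adults.  Drift directions reproduce the
  qualitative compositional shifts that motivate the change decomposition;
* suicides: Poisson totals at 14 per 100,000 (so roughly half of
  stratum-year cells record none -- the sparsity that motivates smoothing),
  firearm fraction `logit q = 0.75 + logit p + offsets` with
  method-preference offsets (woman -0.25, unmarried +0.4, other race +0.5,
  urban +0.35) that make FSS a *systematically biased* proxy of the
  constructed signs.

The generator draws simple random samples within waves; it does not emulate
real survey designs (clustering, random-digit dialling, nonresponse
weighting), ICD cause-coding, or migration between strata.  Passing
recovery tests therefore demonstrates that the pipeline's logic and
uncertainty propagation are sound under known truth -- not that the field
surveys themselves are unbiased.

## Decompositions

For a unit (state or nation) with stratum rates `p_s(t)` and
population-share weights `w_s(t)`, the 1990-to-2018 change splits as

```
total       = sum w_s(y1) p_s(y1) - sum w_s(y0) p_s(y0)
rate        = sum w_s(y0) [p_s(y1) - p_s(y0)]     # composition held at y0
composition = total - rate
```

Component 2 is a residual by construction, matching the asymmetric
"held constant at 1990" framing; a symmetric average-of-endpoints variant
is available behind `symmetric = TRUE` as a robustness check.  The additive
identity holds to machine precision for every unit and per posterior draw.

The cross-sectional analogue compares a state with the nation in one year
over the 16 shared demographic cells: the composition part applies the
state-minus-national weight difference to national cell rates; the rate
part is the remainder.

### Variance partition

Posterior-mean stratum-year estimates are regressed on six factor groups
(state, race, gender, marital status, urbanicity, year-as-factor).  The
main-effects R-squared is attributed to groups by LMG/Shapley averaging of
marginal R-squared gains over all orderings, computed from the 64 subset
fits; contributions are order-invariant, nonnegative for these balanced-ish
designs and sum to the total exactly.  With correlated factor groups
(urbanicity is partially confounded with state because urban-free states
have no urban strata), LMG necessarily shares a small part of a
state-driven signal with its correlates; an exact-recovery property holds
on balanced frames.  An optional interaction list (default gender x marital)
reports the R-squared after augmenting the main effects, and a
population-weighted variant is available.

## Proxy calibration

The FSS proxy is the least-squares linear map from state-year raw FSS to
state-year HFR posterior means over the 1,450 state-years (OLS, verified
against the closed form `slope = cov/var` at 1e-10).  Residuals
`proxy - HFR` (positive = proxy overestimates ownership) are averaged per
state and per demographic group; group FSS sums suicide counts to the group
before dividing, group HFR is poststratified to the same group.  HFR
posterior uncertainty is not propagated into the OLS, and residual
averages over years are unweighted -- both choices documented as defaults
where the published analysis is silent.

## Numerical and degenerate-input policy

* Probabilities returned by engines are clamped to (1e-9, 1 - 1e-9); all
  posterior draws are strictly inside (0, 1).
* Credible intervals are equal-tailed percentile intervals.
* Zero-suicide cells are flagged `defined = FALSE` in raw FSS, never 0.
* An all-zero suicide table, a constant outcome, constant FSS, and empty
  target populations are hard errors with named causes.
* Degenerate variance-partition factors (a single observed level) are
  dropped with a warning rather than producing rank-deficient fits.
* Every stochastic stage takes an explicit seed; identical config + seed
  reproduces every output byte-for-byte (the pipeline manifest records the
  seed and a config checksum).

## Problem sizes used in the shipped checks

The default synthetic study (744 strata x 29 years, 37,400 respondents,
~20,000 suicides, 50-tree engines, 500 draws) runs in about 90 seconds;
the full test suite, which fits it once and reuses it across end-to-end
checks, completes in a few minutes on one CPU.  Scaling experiments in the
tests use reduced frames (subsets of states) and shorter windows; the
constant-truth smoother check uses Poisson mean 600 suicides per cell,
the magnitude at which aggregated real state-year counts operate.

## Known limitations

* The Gaussian approximation of the hierarchical fallback understates
  posterior skew in tiny strata; the tree engine is the reference.
* BART with many near-irrelevant binary covariates tracks some binomial
  noise at very sparse cells; smoothed FSS from sparse tables is best used
  comparatively (its intended role as a covariate), not as a precise cell
  estimate.
* The state-vs-national decomposition ignores within-cell state-by-demographic
  interactions beyond the 16 shared cells.
* No design-based variance: only posterior uncertainty is propagated.
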