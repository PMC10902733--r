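# firearmMRP

Small-area estimation of **HFR** — the proportion of individuals living in
households with a firearm — across US states, years (1990–2018) and
demographic subgroups, for researchers studying firearm exposure, suicide
and policy.  No survey measures HFR at that resolution: a small in-person
survey asks the question in 16 waves, a large telephone survey in only
three years, and most state–demographic cells are empty in most years.
The package estimates the full surface by **multilevel regression and
poststratification (MRP)** and audits the field's standard proxy — the
fraction of suicides committed with a firearm (**FSS**) — against it.

## What it computes

Respondents are modelled with a probit **Bayesian additive regression
trees** (BART) ensemble implemented in the package (`src/bart.cpp`,
Albert–Chib augmentation, standard sum-of-trees prior, fitted on binomial
cells so cost scales with cells rather than respondents):

```
P(firearm in household) = pnorm( f(year, state, gender, marital, race,
                                    urbanicity, survey, smoothed FSS) )
```

Posterior draws of the stratum-year surface `p_s(t)` over the **744
analytic strata** (state × gender × marital × race/ethnicity × urbanicity;
seven states without a large densely populated county contribute only
nonurban strata) are averaged with poststratification weights
`w_s(t) ∝ population(s, t)`:

* `poststratify()` / `estimate_panel()` — population estimates with
  equal-tailed 95% credible intervals for any margin (national, state,
  subgroup, intersections);
* `decompose_temporal()` — Kitagawa-style split of a unit's HFR change,
  `total = Σw₁p₁ − Σw₀p₀`, into a rate component (`Σw₀(p₁−p₀)`, composition
  held at 1990) and a composition remainder; `decompose_state_vs_national()`
  is the cross-sectional analogue;
* `variance_partition()` — LMG/Shapley attribution of the estimate
  surface's main-effects R² to state, race, gender, marital status,
  urbanicity and year;
* `fit_linear_proxy()` and the `proxy_bias_*` functions — the least-squares
  linear map FSS → HFR over 1450 state-years and its systematic state and
  demographic residual biases;
* `fit_fss_smoother()` — the auxiliary BART producing *smoothed FSS* for
  every stratum-year (defined even where no suicides occurred), used as a
  model covariate;
* a `synth_config()`-driven generator producing survey microdata,
  drifting population tables and suicide counts from a known truth
  surface, so the whole pipeline is testable without restricted data.

## Worked example

The default synthetic study (744 strata × 29 years; 16 in-person waves of
1,400 + three telephone years of 5,000 respondents; ~20,000 suicides with
~48% of stratum-year cells empty) runs end to end in about 90 seconds:

```r
library(firearmMRP)

cfg   <- synth_config(seed = 1)
frame <- build_strata_frame()
truth <- generate_truth_surface(cfg, frame)
pop   <- generate_population(cfg, frame)
micro <- simulate_survey_microdata(truth, pop, cfg, frame)
sui   <- simulate_suicide_counts(truth, pop, cfg, frame)

smoothed <- fit_fss_smoother(sui, frame, cfg$years, engine = "bart", seed = 11)
design   <- assemble_design(micro, smoothed, frame, cfg$years)
fit      <- fit_hfr_model(design, engine = "bart", seed = 22)
post     <- predict_strata_probabilities(fit, frame, cfg$years, smoothed)

estimate_panel(post, pop, frame, list(NULL), c(1990, 2004, 2018))
#>     target year estimate lower upper
#> 1 national 1990    0.495 0.482 0.507
#> 2 national 2004    0.443 0.434 0.457
#> 3 national 2018    0.404 0.391 0.417

poststratified_truth(truth, pop, frame, years = c(1990, 2004, 2018))
#>   year truth
#> 1 1990 0.497
#> 2 2004 0.445
#> 3 2018 0.395
```

The model recovers the generator's national series within ~1 percentage
point.  The change decomposition attributes most of the synthetic decline
to composition drift (the generator's demographic mix shifts toward
low-ownership groups while within-stratum rates fall slowly):

```r
decompose_temporal(post, pop, frame, NULL, 1990, 2018)
#>       unit year0 year1   total rate_component composition_component composition_share
#> 1 national  1990  2018 -0.0909        -0.0345               -0.0563              0.62

variance_partition(posterior_mean_surface(post), frame, cfg$years)
#> variance_partition: main-effects R^2 = 0.9129
#>      state       race urbanicity    marital     gender       year
#>     0.3697     0.1918     0.1357     0.1216     0.0902     0.0038
#> with interactions: gender:marital = 0.9274
```

State effects dominate the surface and year contributes least, while
adding the gender × marital interaction raises R² by ~1.5 points —
the qualitative structure the method is designed to expose.  The proxy
audit fits the best linear FSS → HFR map over state-years and shows the
method-preference offsets built into the generator as signed residual
biases:

```r
fss_sy <- compute_raw_fss(sui, by = c("state", "year"))
est_sy <- estimate_panel(post, pop, frame, sort(unique(frame$state)), cfg$years)
est_sy$state <- sub("^state=", "", est_sy$target)
cal <- fit_linear_proxy(fss_sy, est_sy)
#> 1 unit(s) with undefined FSS excluded
cal
#> proxy_calibration: proxy = 0.1526 + 0.4256 * FSS over 1449 state-years (r = 0.601)

head(proxy_bias_by_state(cal), 3)   # proxy underestimates these states
#>   state n_years   bias
#> 1    WA      29 -0.220
#> 2    SC      29 -0.201
#> 3    NH      29 -0.135
```

`run_pipeline(pipeline_config(outdir, seed))` executes all stages in order
and writes the estimate panels, decompositions, variance partition, proxy
calibration and a manifest (seed, settings, row counts, config checksum)
as CSV/JSON; reruns with the same config are byte-identical.

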