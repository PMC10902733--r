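test_that("truth surface reflects its generating coefficients", {
  frame <- build_strata_frame(tiny_metadata(3, 1))
  cfg0 <- synth_config(seed = 5, intercept = 0, gender_man = 0, married = 0,
                       woman_married = 0, race_white_aian = 0, nonurban = 0,
                       year_trend = 0, state_sd = 0)
  tr0 <- generate_truth_surface(cfg0, frame)
  expect_true(all(tr0$p == 0.5))

  # negative year trend: national truth-weighted mean declines monotonically
  cfg <- synth_config(seed = 5)
  tr <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  nat <- poststratified_truth(tr, pop, frame)$truth
  expect_true(all(diff(nat) < 0))
  expect_true(all(tr$p > 0 & tr$p < 1))

  # determinism
  expect_identical(tr, generate_truth_surface(cfg, frame))

  # married women shifted toward married men (interaction nonzero by default)
  i_mw <- which(frame$gender == "woman" & frame$marital == "married")
  i_uw <- which(frame$gender == "woman" & frame$marital == "not_married")
  expect_gt(mean(qlogis(tr$p[i_mw, 1])) - mean(qlogis(tr$p[i_uw, 1])),
            cfg$married)
})

test_that("population drift moves urban, unmarried and minority shares up", {
  frame <- build_strata_frame(tiny_metadata(4, 1))
  cfg <- synth_config(seed = 9)
  pop <- generate_population(cfg, frame)
  share <- function(y, sel) {
    py <- pop[pop$year == y, ]
    m <- match_strata(frame, py)
    sum(py$population[sel[m]]) / sum(py$population)
  }
  urban_states <- unique(frame$state[frame$urbanicity == "urban"])
  for (st in urban_states) {
    sel_urb <- frame$urbanicity == "urban" & frame$state == st
    sel_st <- frame$state == st
    py0 <- pop[pop$year == 1990 & pop$state == st, ]
    py1 <- pop[pop$year == 2018 & pop$state == st, ]
    expect_gt(sum(py1$population[py1$urbanicity == "urban"]) / sum(py1$population),
              sum(py0$population[py0$urbanicity == "urban"]) / sum(py0$population))
  }
  expect_gt(share(2018, frame$marital == "not_married"),
            share(1990, frame$marital == "not_married"))
  expect_gt(share(2018, frame$race == "other"), share(1990, frame$race == "other"))

  # zero drift: identical shares at both ends
  cfg0 <- synth_config(seed = 9, drift_unmarried = 0, drift_minority = 0,
                       drift_urban = 0)
  pop0 <- generate_population(cfg0, frame)
  expect_identical(pop0$population[pop0$year == 1990],
                   pop0$population[pop0$year == 2018])

  # stratum populations within a state-year account for the whole state
  tot <- tapply(pop$population, pop[c("state", "year")], sum)
  expect_true(all(abs(tot - tot[, 1]) <= nrow(frame)))  # rounding only

  # invalid drift rejected
  expect_error(synth_config(drift_urban = 0.02), "outside")
})

test_that("microdata sampling matches the truth surface", {
  frame <- build_strata_frame(tiny_metadata(2, 0))
  cfg <- synth_config(seed = 13, mode_offset = 0,
                      small_survey_n = rep(0L, 16),
                      large_survey_n = rep(40000L, 3),
                      state_pop_mean = 1e6)
  truth <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  md <- simulate_survey_microdata(truth, pop, cfg, frame)
  # waves with n = 0 are absent
  expect_setequal(unique(md$year), cfg$large_survey_years)
  # pooled sample proportion within 3 SE of the truth-weighted mean
  expected <- mean(vapply(cfg$large_survey_years, function(y)
    poststratified_truth(truth, pop, frame, years = y)$truth, numeric(1)))
  phat <- mean(md$response)
  se <- sqrt(expected * (1 - expected) / nrow(md))
  expect_lt(abs(phat - expected), 3 * se + 1e-3)
  # byte-identical under the same seed
  expect_identical(md, simulate_survey_microdata(truth, pop, cfg, frame))
  # oversized wave rejected
  cfg_big <- synth_config(seed = 13, state_pop_mean = 100,
                          large_survey_n = rep(1e6, 3))
  truth2 <- generate_truth_surface(cfg_big, frame)
  pop2 <- generate_population(cfg_big, frame)
  expect_error(simulate_survey_microdata(truth2, pop2, cfg_big, frame),
               "exceeds total population")
})

test_that("suicide counts follow the biased firearm-fraction link", {
  frame <- build_strata_frame(tiny_metadata(3, 1))
  cfg <- synth_config(seed = 17)
  truth <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  sui <- simulate_suicide_counts(truth, pop, cfg, frame)
  expect_true(all(sui$firearm_suicides <= sui$suicides))
  expect_true(all(sui$suicides >= 0))

  # near-zero rate: almost all counts zero
  cfg0 <- synth_config(seed = 17, suicide_rate = 1e-9)
  sui0 <- simulate_suicide_counts(truth, pop, cfg0, frame)
  expect_gt(mean(sui0$suicides == 0), 0.999)

  # identity link chain: alpha0 = 0, alpha1 = 1, no offsets -> q == truth
  cfg1 <- synth_config(seed = 17, fss_alpha0 = 0, fss_alpha1 = 1,
                       fss_offsets = c(woman = 0, not_married = 0,
                                       other = 0, urban = 0))
  q <- true_firearm_fraction(truth, cfg1, frame)
  expect_equal(q, truth$p, tolerance = 1e-12)

  # race method-preference offset separates raw group FSS at equal truth
  cfg2 <- synth_config(seed = 17, suicide_rate = 5e-3, intercept = -1,
                       gender_man = 0, married = 0, woman_married = 0,
                       race_white_aian = 0, nonurban = 0, state_sd = 0,
                       fss_offsets = c(woman = 0, not_married = 0,
                                       other = 1, urban = 0))
  tr2 <- generate_truth_surface(cfg2, frame)
  sui2 <- simulate_suicide_counts(tr2, pop, cfg2, frame)
  g <- compute_raw_fss(sui2, by = "race")
  expect_gt(g$fss[g$race == "other"], g$fss[g$race == "white_aian"])
})

test_that("default suicide sparsity motivates smoothing", {
  st <- default_study()
  expect_gt(mean(st$suicides$suicides == 0), 0.30)
})

test_that("fixture writer emits a complete readable dataset", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 23, small_survey_n = rep(30L, 16),
                      large_survey_n = rep(60L, 3))
  paths <- synth_fixtures(dir, cfg)
  expect_true(all(file.exists(unlist(paths))))
  md <- read_microdata_csv(paths$microdata, cfg$years)
  pop <- read_population_csv(paths$population, cfg$years)
  sui <- read_suicide_csv(paths$suicides, cfg$years)
  expect_equal(nrow(md), sum(cfg$small_survey_n) + sum(cfg$large_survey_n))
  expect_equal(nrow(pop), 744 * length(cfg$years))
  expect_equal(nrow(sui), nrow(pop))
})
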