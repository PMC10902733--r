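const_fss <- function(frame, years, value = 0.5) {
  structure(list(values = matrix(value, nrow(frame), length(years),
                                 dimnames = list(NULL, years)),
                 years = years, engine = "fixture", seed = 0L),
            class = "smoothed_fss")
}

make_records <- function(frame, n, years = 2000, p = 0.4, seed = 1) {
  set.seed(seed)
  s <- sample.int(nrow(frame), n, replace = TRUE)
  data.frame(year = years[sample.int(length(years), n, replace = TRUE)],
             survey = sample(c("in_person", "telephone"), n, replace = TRUE),
             frame[s, firearmMRP:::.strata_fields],
             response = rbinom(n, 1, p), row.names = NULL)
}

test_that("design assembly drops bad records with counted reasons", {
  frame <- build_strata_frame(tiny_metadata(3, 1))
  years <- 1999:2001
  rec <- make_records(frame, 10, years)
  sm <- const_fss(frame, years)
  des <- assemble_design(rec, sm, frame, years)
  expect_equal(nrow(des$data), 10)
  expect_equal(sum(des$dropped), 0)

  rec2 <- rec
  rec2$state[1] <- "ZZ"            # unknown code
  rec2$response[2] <- NA           # missing field
  rec2$year[3] <- 1950             # out of window
  des2 <- assemble_design(rec2, sm, frame, years)
  expect_equal(nrow(des2$data), 7)
  expect_equal(unname(des2$dropped["unknown_code"]), 1L)
  expect_equal(unname(des2$dropped["missing_field"]), 1L)
  expect_equal(unname(des2$dropped["year_out_of_window"]), 1L)

  # smoothed FSS joined exactly on stratum-year keys
  sm2 <- const_fss(frame, years)
  sm2$values[] <- seq_along(sm2$values) / (length(sm2$values) + 1)
  des3 <- assemble_design(rec, sm2, frame, years)
  pos <- match_strata(frame, des3$data)
  yi <- match(des3$data$year, years)
  expect_identical(des3$data$fss, sm2$values[cbind(pos, yi)])

  # missing grid cell is a named error
  sm3 <- const_fss(frame, 1999:2000)
  expect_error(assemble_design(rec[rec$year == 2001, ], sm3, frame, years),
               "no smoothed FSS value")
})

test_that("model fitting validates its inputs", {
  frame <- build_strata_frame(tiny_metadata(3, 1))
  rec <- make_records(frame, 20)
  sm <- const_fss(frame, 2000)
  rec$response <- 1L
  des <- assemble_design(rec, sm, frame, 2000)
  expect_error(fit_hfr_model(des), "constant outcome")
})

test_that("tree-ensemble posterior is reproducible and proper", {
  frame <- build_strata_frame(tiny_metadata(3, 1))
  years <- 2000:2002
  cfg <- synth_config(seed = 43, years = 1990:2010,
                      small_survey_years = years,
                      small_survey_n = rep(80L, 3),
                      large_survey_years = 2001, large_survey_n = 200L)
  truth <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  rec <- simulate_survey_microdata(truth, pop, cfg, frame)
  sm <- const_fss(frame, years)
  des <- assemble_design(rec, sm, frame, years)
  st <- engine_settings(ntree = 20, nburn = 80, ndraw = 80)
  fit <- fit_hfr_model(des, "bart", st, seed = 5)
  post <- predict_strata_probabilities(fit, frame, years, sm)
  expect_equal(dim(post$draws), c(80, nrow(frame), 3))
  expect_true(all(post$draws > 0 & post$draws < 1))

  fit2 <- fit_hfr_model(des, "bart", st, seed = 5)
  post2 <- predict_strata_probabilities(fit2, frame, years, sm)
  expect_identical(post$draws, post2$draws)

  # strata with no respondents in a year still get predictions
  seen <- unique(paste(match_strata(frame, rec), rec$year))
  all_cells <- expand.grid(s = seq_len(nrow(frame)), y = years)
  empty <- !(paste(all_cells$s, all_cells$y) %in% seen)
  expect_gt(sum(empty), 0)
  expect_true(all(is.finite(post$draws)))
})

test_that("duplicating the data narrows intervals without moving the estimate", {
  frame <- build_strata_frame(tiny_metadata(2, 0))
  years <- 2000
  cfg <- synth_config(seed = 47, years = 1995:2005,
                      small_survey_years = years, small_survey_n = 2000L,
                      large_survey_years = 2001, large_survey_n = 0L)
  truth <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  rec <- simulate_survey_microdata(truth, pop, cfg, frame)
  sm <- const_fss(frame, years)
  st <- engine_settings(ntree = 20, nburn = 100, ndraw = 150)
  des1 <- assemble_design(rec, sm, frame, years)
  des2 <- assemble_design(rbind(rec, rec), sm, frame, years)
  f1 <- fit_hfr_model(des1, "bart", st, seed = 5)
  f2 <- fit_hfr_model(des2, "bart", st, seed = 5)
  p1 <- predict_strata_probabilities(f1, frame, years, sm)
  p2 <- predict_strata_probabilities(f2, frame, years, sm)
  e1 <- poststratify(p1, pop, frame, NULL, years)
  e2 <- poststratify(p2, pop, frame, NULL, years)
  expect_lt(abs(e1$estimate - e2$estimate), 0.02)
  expect_lt(e2$upper - e2$lower, e1$upper - e1$lower)
})

test_that("fallback and tree engines agree on the national estimate", {
  frame <- build_strata_frame(tiny_metadata(4, 1))
  cfg <- synth_config(seed = 53, woman_married = 0,   # main-effects generator
                      small_survey_n = rep(500L, 16),
                      large_survey_n = rep(1500L, 3))
  truth <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  rec <- simulate_survey_microdata(truth, pop, cfg, frame)
  sm <- const_fss(frame, cfg$years)
  des <- assemble_design(rec, sm, frame, cfg$years, include_fss = FALSE)
  st <- engine_settings(ntree = 30, nburn = 150, ndraw = 200)
  fb <- fit_hfr_model(des, "bart", st, seed = 5)
  fh <- fit_hfr_model(des, "hierarchical", st, seed = 5)
  pb <- predict_strata_probabilities(fb, frame, cfg$years)
  ph <- predict_strata_probabilities(fh, frame, cfg$years)
  for (y in c(1990, 2004, 2018)) {
    eb <- poststratify(pb, pop, frame, NULL, y)$estimate
    eh <- poststratify(ph, pop, frame, NULL, y)$estimate
    expect_lt(abs(eb - eh), 0.03)
  }
})

test_that("the model runs without the smoothed FSS covariate", {
  frame <- build_strata_frame(tiny_metadata(2, 0))
  rec <- make_records(frame, 400, 2000:2001, p = 0.35)
  des <- assemble_design(rec, NULL, frame, 2000:2001, include_fss = FALSE)
  fit <- fit_hfr_model(des, "bart", engine_settings(ntree = 10, nburn = 40,
                                                    ndraw = 40), seed = 3)
  post <- predict_strata_probabilities(fit, frame, 2000:2001)
  expect_true(all(post$draws > 0 & post$draws < 1))
  expect_equal(dim(post$draws)[2:3], c(nrow(frame), 2))
})
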