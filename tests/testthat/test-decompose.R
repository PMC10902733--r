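two_strata_setup <- function() {
  frame <- build_strata_frame(tiny_metadata(1, 1))  # 8 strata, one state
  years <- c(1990, 2018)
  # use the first two strata; the rest get zero population
  p <- matrix(0, nrow(frame), 2)
  p[1, ] <- c(0.6, 0.5); p[2, ] <- c(0.2, 0.2)
  post <- fake_posterior(frame, years, p = p)
  pop <- uniform_population(frame, years, count = 0)
  pop$population[pop$year == 1990][1:2] <- c(500L, 500L)
  pop$population[pop$year == 2018][1:2] <- c(300L, 700L)
  list(frame = frame, years = years, post = post, pop = pop)
}

test_that("temporal decomposition reproduces the hand-checked example", {
  s <- two_strata_setup()
  d <- decompose_temporal(s$post, s$pop, s$frame, NULL, 1990, 2018)
  # w0=(.5,.5), w1=(.3,.7), p0=(.6,.2), p1=(.5,.2):
  # total = .29-.40 = -.11, rate = .5*(-.1) = -.05, composition = -.06
  expect_equal(d$total, -0.11, tolerance = 1e-12)
  expect_equal(d$rate_component, -0.05, tolerance = 1e-12)
  expect_equal(d$composition_component, -0.06, tolerance = 1e-12)
  expect_equal(d$composition_share, 0.06 / 0.11, tolerance = 1e-12)

  # brute-force recomputation from first principles
  w0 <- c(.5, .5); w1 <- c(.3, .7); p0 <- c(.6, .2); p1 <- c(.5, .2)
  expect_equal(d$total, sum(w1 * p1) - sum(w0 * p0))
  expect_equal(d$rate_component, sum(w0 * (p1 - p0)))
})

test_that("degenerate decompositions vanish on the right side", {
  s <- two_strata_setup()
  # rates constant over time -> rate component 0
  pconst <- s$post
  pconst$draws[, , 2] <- pconst$draws[, , 1]
  d1 <- decompose_temporal(pconst, s$pop, s$frame, NULL, 1990, 2018)
  expect_equal(d1$rate_component, 0, tolerance = 1e-12)
  expect_equal(d1$composition_component, d1$total, tolerance = 1e-12)

  # weights constant -> composition component 0
  popc <- s$pop
  popc$population[popc$year == 2018] <- popc$population[popc$year == 1990]
  d2 <- decompose_temporal(s$post, popc, s$frame, NULL, 1990, 2018)
  expect_equal(d2$composition_component, 0, tolerance = 1e-12)
})

test_that("decomposition identities hold for every state on a synthetic run", {
  st <- default_study()
  dec <- decompose_all_states(st$post, st$pop, st$frame, 1990, 2018)
  expect_equal(nrow(dec), 50)
  expect_lt(max(abs(dec$total - dec$rate_component - dec$composition_component)),
            1e-12)
  svn <- do.call(rbind, lapply(sort(unique(st$frame$state)), function(s)
    decompose_state_vs_national(st$post, st$pop, st$frame, s, 2018)))
  expect_lt(max(abs(svn$total - svn$rate_component - svn$composition_component)),
            1e-12)
  # direct difference check
  nat <- poststratify(st$post, st$pop, st$frame, NULL, 2018)$estimate
  mt <- poststratify(st$post, st$pop, st$frame, list(state = "MT"), 2018)$estimate
  expect_equal(svn$total[svn$unit == "MT"], mt - nat, tolerance = 1e-12)
})

test_that("per-draw decomposition matches the point decomposition", {
  st <- default_study()
  d <- decompose_temporal(st$post, st$pop, st$frame, NULL, 1990, 2018,
                          draws = TRUE)
  dm <- d$draw_means[[1]]
  expect_lt(abs(dm["total"] - d$total), 0.01)
  expect_lt(abs(dm["rate"] - d$rate_component), 0.01)
  expect_true(d$total_lower <= d$total && d$total <= d$total_upper)
})

test_that("strong composition drift with flat rates is attributed to composition", {
  frame <- build_strata_frame(tiny_metadata(4, 1))
  cfg <- synth_config(seed = 67, year_trend = 0,
                      drift_unmarried = 0.008, drift_minority = 0.008,
                      drift_urban = 0.008, share_urban0 = 0.35)
  truth <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  post <- fake_posterior(frame, cfg$years, p = truth$p, ndraw = 2)
  for (s in unique(frame$state)) {
    d <- decompose_temporal(post, pop, frame, list(state = s), 1990, 2018)
    expect_lt(d$total, 0)
    expect_gt(d$composition_component / d$total, 0.9)
  }
})

test_that("state-vs-national components vanish in the matched cases", {
  frame <- build_strata_frame(tiny_metadata(3, 0))
  years <- 2018
  # identical rates and composition everywhere: both components zero
  p <- matrix(0.35, nrow(frame), 1)
  post <- fake_posterior(frame, years, p = p)
  pop <- uniform_population(frame, years, count = 100)
  d <- decompose_state_vs_national(post, pop, frame, "AL", 2018)
  expect_equal(d$total, 0, tolerance = 1e-12)
  expect_equal(d$rate_component, 0, tolerance = 1e-12)

  # national rates, composition skewed toward high-rate cells: rate part 0
  p2 <- matrix(0.2, nrow(frame), 1)
  p2[frame$gender == "man", 1] <- 0.5   # rates depend on cell, not state
  post2 <- fake_posterior(frame, years, p = p2)
  pop2 <- pop
  sel <- pop2$state == "AL" & pop2$gender == "man"
  pop2$population[sel] <- 400L
  d2 <- decompose_state_vs_national(post2, pop2, frame, "AL", 2018)
  expect_equal(d2$rate_component, 0, tolerance = 1e-12)
  expect_gt(d2$composition_component, 0)
})

test_that("variance partition attributes known generators correctly", {
  # balanced frame (every state urban-capable) so the factor groups are
  # orthogonal and a pure state effect is attributable exactly
  frame <- build_strata_frame(tiny_metadata(6, 0))
  years <- 2000:2004
  set.seed(71)
  # pure state effects
  st_eff <- setNames(runif(6, 0.2, 0.6), sort(unique(frame$state)))
  surf <- matrix(st_eff[frame$state], nrow(frame), length(years))
  vp <- variance_partition(surf, frame, years)
  expect_equal(unname(vp$contributions["state"]), vp$total_r2,
               tolerance = 1e-8)
  expect_lt(sum(vp$contributions[setdiff(names(vp$contributions), "state")]),
            1e-8)
  # LMG contributions sum to the main-effects R^2
  expect_lt(abs(sum(vp$contributions) - vp$total_r2), 1e-10)

  # mixed surface: interactions never decrease R^2, contributions sum
  surf2 <- surf + outer(0.3 * (frame$gender == "man") +
                          0.15 * (frame$marital == "married") +
                          0.1 * (frame$gender == "man") *
                          (frame$marital == "married"),
                        seq_along(years) * 0.01)
  vp2 <- variance_partition(surf2, frame, years)
  expect_gte(vp2$r2_with_interactions[["gender:marital"]], vp2$total_r2)
  expect_lt(abs(sum(vp2$contributions) - vp2$total_r2), 1e-10)
  expect_true(all(vp2$contributions >= -1e-12))
})

test_that("degenerate factors are dropped with a warning", {
  frame <- build_strata_frame(tiny_metadata(2, 2))  # all nonurban
  years <- 2000
  surf <- matrix(runif(nrow(frame)), nrow(frame), 1)
  expect_warning(vp <- variance_partition(surf, frame, years),
                 "urbanicity")
  expect_false("urbanicity" %in% names(vp$contributions))
})
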