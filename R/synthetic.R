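# Synthetic survey-study generator: a known truth surface over strata-years,
# drifting population composition, two survey modes, and suicide counts whose
# firearm fraction is a biased transform of true ownership.  Every downstream
# stage is validated against this generator.

.survey_codes <- c("in_person", "telephone")

# in-person survey administration years, 16 waves 1990-2018
.small_wave_years <- c(1990, 1991, 1993, 1994, 1996, 1998, 2000, 2002,
                       2004, 2006, 2008, 2010, 2012, 2014, 2016, 2018)

#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic generator.  The defaults emulate
#' the study design: a small in-person survey fielded in 16 waves over
#' 1990-2018, a large telephone survey fielded in 2001, 2002 and 2004,
#' population composition drifting toward urban/unmarried/minority, and
#' suicide counts sparse enough that over 30% of stratum-years record none.
#'
#' @param seed Integer seed governing every stochastic draw.
#' @param scale `"desk"` (16 x 1400 + 3 x 5000 respondents, state adult
#'   populations averaging 1e5) or `"full"` (per-wave sizes matching the
#'   source surveys: 22,430 in-person + 691,028 telephone = 713,458).
#' @param years Study window (inclusive).
#' @param small_survey_years,small_survey_n In-person wave years and sizes.
#' @param large_survey_years,large_survey_n Telephone years and sizes.
#' @param mode_offset Log-odds shift applied to telephone responses; truth is
#'   defined at the in-person (mode-free) level.
#' @param intercept,gender_man,married,woman_married,race_white_aian,nonurban,year_trend
#'   Log-odds coefficients of the truth surface (reference: unmarried urban
#'   woman of the non-White/AIAN group, 1990).  `woman_married` is the
#'   gender x marital interaction lifting married women toward married men.
#' @param state_sd SD of mean-zero Gaussian state effects (log-odds).
#' @param state_pop_mean Mean adult population per state.
#' @param state_pop_lsd Log-scale SD of state population sizes.
#' @param share_man Male share of each state-year population (constant).
#' @param share_married0,share_white0,share_urban0 Margin shares in 1990.
#' @param drift_unmarried,drift_minority,drift_urban Linear per-year increase
#'   in the unmarried, minority and urban shares (positive = rising).
#' @param suicide_rate Annual suicides per person.
#' @param fss_alpha0,fss_alpha1 Link from true ownership to the firearm
#'   fraction among suicides: `logit q = alpha0 + alpha1 logit p + offsets`.
#' @param fss_offsets Named log-odds method-preference offsets
#'   (`woman`, `not_married`, `other`, `urban`) applied to q; these create the
#'   systematic proxy biases the calibration module is built to detect.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         scale = c("desk", "full"),
                         years = 1990:2018,
                         small_survey_years = .small_wave_years,
                         small_survey_n = NULL,
                         large_survey_years = c(2001L, 2002L, 2004L),
                         large_survey_n = NULL,
                         mode_offset = 0.15,
                         intercept = -2.6,
                         gender_man = 1.1,
                         married = 0.45,
                         woman_married = 0.75,
                         race_white_aian = 1.0,
                         nonurban = 0.9,
                         year_trend = -0.008,
                         state_sd = 0.6,
                         state_pop_mean = 1e5,
                         state_pop_lsd = 0.6,
                         share_man = 0.49,
                         share_married0 = 0.58,
                         share_white0 = 0.76,
                         share_urban0 = 0.45,
                         drift_unmarried = 0.004,
                         drift_minority = 0.004,
                         drift_urban = 0.004,
                         suicide_rate = 14e-5,
                         fss_alpha0 = 0.75,
                         fss_alpha1 = 1.0,
                         fss_offsets = c(woman = -0.25, not_married = 0.4,
                                         other = 0.5, urban = 0.35)) {
  scale <- match.arg(scale)
  if (is.null(small_survey_n))
    small_survey_n <- if (scale == "full")
      c(1401L, 1401L, rep(1402L, 14L)) else rep(1400L, 16L)
  if (is.null(large_survey_n))
    large_survey_n <- if (scale == "full")
      c(192700L, 221920L, 276408L) else rep(5000L, 3L)
  cfg <- list(seed = as.integer(seed), scale = scale, years = years,
              small_survey_years = small_survey_years,
              small_survey_n = small_survey_n,
              large_survey_years = large_survey_years,
              large_survey_n = large_survey_n,
              mode_offset = mode_offset, intercept = intercept,
              gender_man = gender_man, married = married,
              woman_married = woman_married,
              race_white_aian = race_white_aian, nonurban = nonurban,
              year_trend = year_trend, state_sd = state_sd,
              state_pop_mean = state_pop_mean, state_pop_lsd = state_pop_lsd,
              share_man = share_man, share_married0 = share_married0,
              share_white0 = share_white0, share_urban0 = share_urban0,
              drift_unmarried = drift_unmarried,
              drift_minority = drift_minority, drift_urban = drift_urban,
              suicide_rate = suicide_rate, fss_alpha0 = fss_alpha0,
              fss_alpha1 = fss_alpha1, fss_offsets = fss_offsets)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg A `synth_config`.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$years) >= 1, !is.unsorted(cfg$years))
  if (!all(cfg$small_survey_years %in% cfg$years) ||
      !all(cfg$large_survey_years %in% cfg$years))
    stop("survey wave years must lie within the study window")
  if (length(cfg$small_survey_n) != length(cfg$small_survey_years))
    stop("small_survey_n must match small_survey_years in length")
  if (length(cfg$large_survey_n) != length(cfg$large_survey_years))
    stop("large_survey_n must match large_survey_years in length")
  if (any(c(cfg$small_survey_n, cfg$large_survey_n) < 0))
    stop("wave sizes must be nonnegative")
  span <- max(cfg$years) - min(cfg$years)
  shares <- rbind(
    c(cfg$share_married0, cfg$share_married0 - span * cfg$drift_unmarried),
    c(cfg$share_white0,   cfg$share_white0   - span * cfg$drift_minority),
    c(cfg$share_urban0,   cfg$share_urban0   + span * cfg$drift_urban))
  if (any(shares <= 0 | shares >= 1))
    stop("composition drift pushes a margin share outside (0, 1)")
  if (cfg$suicide_rate < 0) stop("suicide_rate must be nonnegative")
  cfg
}

# Evaluate an expression under a fixed RNG state, restoring it afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.year_index <- function(years, year) match(year, years)

#' Generate the true ownership surface
#'
#' Builds the probability of living in a household with a firearm for every
#' stratum-year from a logistic surface: intercept + Gaussian state effects +
#' four demographic main effects + a gender x marital interaction + a linear
#' year trend.  Deterministic under `cfg$seed` (the seed governs only the
#' state effects).
#'
#' @param cfg A [synth_config()].
#' @param frame A `strata_frame`.
#' @return A `truth_surface`: list with `p` (strata x years probability
#'   matrix), `years`, `state_effects`, and the generating coefficients.
#' @export
generate_truth_surface <- function(cfg, frame) {
  validate_synth_config(cfg)
  states <- sort(unique(frame$state))
  st_eff <- with_seed(cfg$seed + 101L,
                      setNames(rnorm(length(states), 0, cfg$state_sd), states))
  eta0 <- cfg$intercept + st_eff[frame$state] +
    cfg$gender_man * (frame$gender == "man") +
    cfg$married * (frame$marital == "married") +
    cfg$woman_married * (frame$gender == "woman" & frame$marital == "married") +
    cfg$race_white_aian * (frame$race == "white_aian") +
    cfg$nonurban * (frame$urbanicity == "nonurban")
  yrs <- cfg$years
  p <- vapply(yrs, function(y)
    plogis(eta0 + cfg$year_trend * (y - min(yrs))), numeric(nrow(frame)))
  dimnames(p) <- list(NULL, yrs)
  structure(list(p = p, years = yrs, state_effects = st_eff,
                 coefficients = cfg[c("intercept", "gender_man", "married",
                                      "woman_married", "race_white_aian",
                                      "nonurban", "year_trend")]),
            class = "truth_surface")
}

#' Generate the stratum-by-year population table
#'
#' Stratum shares follow a product of margins (gender, marital, race,
#' urbanicity) with linear drift in the marital, race and urban margins;
#' urban-free states place their whole population in nonurban strata.
#' State adult totals are log-normal around `state_pop_mean` and constant
#' over years.
#'
#' @inheritParams generate_truth_surface
#' @return Data frame: five strata columns, `year`, `population` (integer).
#' @export
generate_population <- function(cfg, frame) {
  validate_synth_config(cfg)
  states <- sort(unique(frame$state))
  lsd <- cfg$state_pop_lsd
  base <- with_seed(cfg$seed + 202L,
    setNames(cfg$state_pop_mean * exp(rnorm(length(states), -lsd^2 / 2, lsd)),
             states))
  has_urban <- tapply(frame$urbanicity == "urban", frame$state, any)[states]
  y0 <- min(cfg$years)
  out <- vector("list", length(cfg$years))
  for (k in seq_along(cfg$years)) {
    y <- cfg$years[k]; d <- y - y0
    s_mar <- cfg$share_married0 - d * cfg$drift_unmarried
    s_wht <- cfg$share_white0 - d * cfg$drift_minority
    s_urb <- ifelse(has_urban[frame$state], cfg$share_urban0 + d * cfg$drift_urban, 0)
    share <- ifelse(frame$gender == "man", cfg$share_man, 1 - cfg$share_man) *
      ifelse(frame$marital == "married", s_mar, 1 - s_mar) *
      ifelse(frame$race == "white_aian", s_wht, 1 - s_wht) *
      ifelse(frame$urbanicity == "urban", s_urb, 1 - s_urb)
    out[[k]] <- data.frame(frame[.strata_fields], year = y,
                           population = as.integer(round(base[frame$state] * share)))
  }
  pop <- do.call(rbind, out)
  rownames(pop) <- NULL
  pop
}

#' Simulate survey microdata
#'
#' Draws respondents for every wave of both surveys: each respondent's
#' stratum is sampled with probability proportional to its population in the
#' wave year, and the binary household-firearm response is Bernoulli with
#' probability `plogis(logit(truth) + mode_offset * telephone)`.
#'
#' @param truth A `truth_surface`.
#' @param pop Population table from [generate_population()].
#' @param cfg The [synth_config()].
#' @param frame The `strata_frame`.
#' @return Data frame: `year`, `survey` (`in_person`/`telephone`), the five
#'   strata columns, `response` (0/1).
#' @export
simulate_survey_microdata <- function(truth, pop, cfg, frame) {
  validate_synth_config(cfg)
  waves <- rbind(
    data.frame(year = cfg$small_survey_years, survey = "in_person",
               n = cfg$small_survey_n),
    data.frame(year = cfg$large_survey_years, survey = "telephone",
               n = cfg$large_survey_n))
  waves <- waves[order(waves$year, waves$survey), , drop = FALSE]
  waves <- waves[waves$n > 0, , drop = FALSE]
  pos <- match_strata(frame, pop)
  with_seed(cfg$seed + 303L, {
    recs <- lapply(seq_len(nrow(waves)), function(i) {
      y <- waves$year[i]; n <- waves$n[i]
      py <- pop$population[pop$year == y]
      cnt <- numeric(nrow(frame))
      cnt[pos[pop$year == y]] <- py
      if (n > sum(cnt)) stop("requested n (", n, ") exceeds total population in ", y)
      s <- sample.int(nrow(frame), n, replace = TRUE, prob = cnt)
      eta <- qlogis(truth$p[s, .year_index(truth$years, y)]) +
        cfg$mode_offset * (waves$survey[i] == "telephone")
      data.frame(year = y, survey = waves$survey[i],
                 frame[s, .strata_fields], response = rbinom(n, 1L, plogis(eta)))
    })
    md <- do.call(rbind, recs)
    rownames(md) <- NULL
    md
  })
}

#' True firearm fraction among suicides
#'
#' The generator's probability that a suicide in a stratum-year used a
#' firearm: `logit q = alpha0 + alpha1 * logit(p) + method-preference
#' offsets`.  This is the recovery target for the FSS smoother.
#'
#' @inheritParams simulate_survey_microdata
#' @return Matrix strata x years of probabilities.
#' @export
true_firearm_fraction <- function(truth, cfg, frame) {
  off <- cfg$fss_offsets[c("woman", "not_married", "other", "urban")]
  extra <- off["woman"] * (frame$gender == "woman") +
    off["not_married"] * (frame$marital == "not_married") +
    off["other"] * (frame$race == "other") +
    off["urban"] * (frame$urbanicity == "urban")
  q <- plogis(cfg$fss_alpha0 + cfg$fss_alpha1 * qlogis(truth$p) + extra)
  dimnames(q) <- dimnames(truth$p)
  q
}

#' Simulate suicide counts
#'
#' Total suicides in a stratum-year are Poisson with mean population x rate;
#' firearm suicides are Binomial given the total with the biased firearm
#' fraction of [true_firearm_fraction()].  At the default (scaled-down)
#' rate a large share of stratum-years records zero suicides, reproducing
#' the sparsity that motivates the FSS smoother.
#'
#' @inheritParams simulate_survey_microdata
#' @return Data frame: five strata columns, `year`, `suicides`,
#'   `firearm_suicides`.
#' @export
simulate_suicide_counts <- function(truth, pop, cfg, frame) {
  validate_synth_config(cfg)
  q <- true_firearm_fraction(truth, cfg, frame)
  pos <- match_strata(frame, pop)
  yi <- .year_index(truth$years, pop$year)
  with_seed(cfg$seed + 404L, {
    tot <- rpois(nrow(pop), pop$population * cfg$suicide_rate)
    fa <- rbinom(nrow(pop), tot, q[cbind(pos, yi)])
    out <- data.frame(pop[.strata_fields], year = pop$year,
                      suicides = tot, firearm_suicides = fa)
    rownames(out) <- NULL
    out
  })
}

#' Poststratified truth for any margin
#'
#' Closed-form population value of the generator's surface: the
#' population-weighted mean of true stratum probabilities over a target
#' selection.  This is the estimand every end-to-end test recovers.
#'
#' @inheritParams simulate_survey_microdata
#' @param target Named-list selector as in [compute_weights()].
#' @param years Years to evaluate (default: all generator years).
#' @return Data frame `year`, `truth`.
#' @export
poststratified_truth <- function(truth, pop, frame, target = NULL,
                                 years = truth$years) {
  vapply(years, function(y) {
    w <- compute_weights(pop, frame, target, y)
    sum(w * truth$p[, .year_index(truth$years, y)])
  }, numeric(1)) -> v
  data.frame(year = years, truth = v)
}

#' Write a complete synthetic fixture set
#'
#' Generates and writes the strata frame, population, microdata, suicide and
#' truth tables as CSV to a directory.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synth_config()].
#' @param state_metadata Metadata table (default packaged).
#' @return Invisibly, the named list of file paths.
#' @export
synth_fixtures <- function(dir, cfg = synth_config(),
                           state_metadata = default_state_metadata()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frame <- build_strata_frame(state_metadata)
  truth <- generate_truth_surface(cfg, frame)
  pop <- generate_population(cfg, frame)
  md <- simulate_survey_microdata(truth, pop, cfg, frame)
  sui <- simulate_suicide_counts(truth, pop, cfg, frame)
  tr <- data.frame(frame[rep(seq_len(nrow(frame)), length(truth$years)),
                         .strata_fields],
                   year = rep(truth$years, each = nrow(frame)),
                   truth = as.vector(truth$p))
  paths <- list(
    strata = file.path(dir, "strata.csv"),
    population = file.path(dir, "population.csv"),
    microdata = file.path(dir, "microdata.csv"),
    suicides = file.path(dir, "suicides.csv"),
    truth = file.path(dir, "truth.csv"))
  write.csv(as.data.frame(frame), paths$strata, row.names = FALSE)
  write.csv(pop, paths$population, row.names = FALSE)
  write.csv(md, paths$microdata, row.names = FALSE)
  write.csv(sui, paths$suicides, row.names = FALSE)
  write.csv(tr, paths$truth, row.names = FALSE)
  invisible(paths)
}
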