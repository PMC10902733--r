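# Engine layer shared by the ownership model and the FSS smoother.
#
# Two engines satisfy the same contract (given covariate rows, return
# posterior draws of P(outcome = 1)):
#   * "bart"         - probit Bayesian additive regression trees (src/bart.cpp)
#   * "hierarchical" - binomial logistic regression with a state random
#                      intercept (lme4), posterior approximated by Gaussians
#                      around the fitted modes

#' Engine settings
#'
#' Tuning knobs for the Bayesian tree ensemble.  `desk` (default) is sized
#' for interactive runs and the packaged synthetic study; `production`
#' raises the tree count and chain length.
#'
#' @param preset `"desk"` or `"production"`.
#' @param ntree Number of trees in the ensemble.
#' @param nburn Burn-in iterations discarded.
#' @param ndraw Posterior draws kept.
#' @param thin Thinning interval between kept draws.
#' @param k Leaf-prior scale: leaf values have sd `3/(k sqrt(ntree))`.
#' @param alpha,beta Tree-depth prior `P(split at depth d) = alpha (1+d)^-beta`.
#' @param numcut Maximum cutpoints per continuous covariate.
#' @return A list of class `engine_settings`.
#' @export
engine_settings <- function(preset = c("desk", "production"),
                            ntree = NULL, nburn = NULL, ndraw = NULL,
                            thin = 1L, k = 2, alpha = 0.95, beta = 2,
                            numcut = 100L) {
  preset <- match.arg(preset)
  def <- if (preset == "desk") c(50L, 300L, 500L) else c(200L, 1000L, 1000L)
  s <- list(ntree = ntree %||% def[1], nburn = nburn %||% def[2],
            ndraw = ndraw %||% def[3], thin = as.integer(thin), k = k,
            alpha = alpha, beta = beta, numcut = as.integer(numcut),
            preset = preset)
  stopifnot(s$ntree >= 1, s$nburn >= 0, s$ndraw >= 1, s$thin >= 1)
  class(s) <- "engine_settings"
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric design matrix shared by both engines and the prediction grid.
# States enter as indicator columns; year is continuous.
.design_matrix <- function(df, states, include_survey = TRUE,
                           include_fss = TRUE) {
  cols <- list(year = as.numeric(df$year))
  for (s in states) cols[[paste0("state_", s)]] <- as.numeric(df$state == s)
  cols$man <- as.numeric(df$gender == "man")
  cols$married <- as.numeric(df$marital == "married")
  cols$white_aian <- as.numeric(df$race == "white_aian")
  cols$urban <- as.numeric(df$urbanicity == "urban")
  if (include_survey) cols$telephone <- as.numeric(df$survey == "telephone")
  if (include_fss) cols$fss <- as.numeric(df$fss)
  do.call(cbind, cols)
}

# Run the probit tree ensemble on binomial cells (trials/successes per
# covariate row) and return posterior probability draws at the prediction
# rows (matrix ndraw x npred).
.run_bart <- function(X, trials, successes, Xpred, settings, seed,
                      verbose = FALSE) {
  offset <- qnorm(clamp01(sum(successes) / sum(trials)))
  with_seed(seed, {
    out <- bart_probit_cpp(X, as.integer(trials), as.integer(successes),
                           Xpred,
                           settings$ntree, settings$nburn, settings$ndraw,
                           settings$thin, settings$alpha, settings$beta,
                           settings$k, settings$numcut, offset, verbose)
    list(pred = clamp01(pnorm(out$pred)),
         train = clamp01(pnorm(out$train)),
         accept_rate = out$accept_rate,
         mean_leaf_depth = out$mean_leaf_depth)
  })
}

# collapse respondent-level rows into binomial cells over identical
# covariate vectors (stratum x year x survey; smoothed FSS is constant
# within such a cell)
.binomial_cells <- function(data) {
  keys <- c("year", "survey", .strata_fields)
  key <- do.call(paste, c(data[keys], sep = "\r"))
  tab <- rowsum(cbind(trials = rep(1L, nrow(data)),
                      successes = data$response), key)
  first <- !duplicated(key)
  cells <- data[first, , drop = FALSE]
  cells <- cells[order(key[first]), , drop = FALSE]
  cells$trials <- tab[, "trials"]
  cells$successes <- tab[, "successes"]
  rownames(cells) <- NULL
  cells
}

clamp01 <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

# Hierarchical-logistic fallback: aggregate to binomial cells, fit a state
# random-intercept GLMM, and draw from independent Gaussian approximations
# to the fixed-effect posterior and the state-effect conditionals.
.fit_hier <- function(data, include_survey = TRUE, include_fss = TRUE) {
  cell_vars <- c("state", "gender", "marital", "race", "urbanicity", "year",
                 if (include_survey) "survey",
                 if (include_fss) "fss")
  agg <- aggregate(list(events = data$response, n = rep(1L, nrow(data))),
                   by = data[cell_vars], FUN = sum)
  agg <- .as_model_factors(agg)
  agg$year_s <- (agg$year - 2004) / 10
  rhs <- c("year_s", "gender", "marital", "race", "urbanicity",
           "gender:marital",
           if (include_survey) "survey",
           if (include_fss) "fss",
           "(1 | state)")
  form <- as.formula(paste("cbind(events, n - events) ~",
                           paste(rhs, collapse = " + ")))
  lme4::glmer(form, data = agg, family = stats::binomial())
}

.as_model_factors <- function(df) {
  for (f in names(.codes)) if (f %in% names(df))
    df[[f]] <- factor(df[[f]], levels = .codes[[f]])
  if ("survey" %in% names(df)) df$survey <- factor(df$survey, levels = .survey_codes)
  if ("state" %in% names(df)) df$state <- factor(df$state)
  df
}

.predict_hier <- function(fit, grid, ndraw, seed) {
  grid <- .as_model_factors(grid)
  grid$year_s <- (grid$year - 2004) / 10
  X <- .hier_fixed_matrix(fit, grid)
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  re <- lme4::ranef(fit, condVar = TRUE)$state
  pv <- attr(re, "postVar")
  re_mean <- setNames(re[, 1], rownames(re))
  re_sd <- setNames(sqrt(pv[1, 1, ]), rownames(re))
  si <- match(grid$state, names(re_mean))
  with_seed(seed, {
    Z <- matrix(rnorm(ndraw * length(beta)), ndraw)
    B <- matrix(beta, ndraw, length(beta), byrow = TRUE) + Z %*% chol(V)
    eta_fix <- B %*% t(X)                       # ndraw x npred
    U <- matrix(rnorm(ndraw * length(re_mean)), ndraw)
    RE <- sweep(sweep(U, 2, re_sd, `*`), 2, re_mean, `+`)
    clamp01(plogis(eta_fix + RE[, si, drop = FALSE]))
  })
}

.hier_fixed_matrix <- function(fit, grid) {
  # model matrix for new data using the fitted fixed-effects terms
  form <- lme4::nobars(stats::formula(fit, fixed.only = TRUE))
  form <- form[-2]  # drop the response
  mm <- stats::model.matrix(form, grid)
  mm[, names(lme4::fixef(fit)), drop = FALSE]
}
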