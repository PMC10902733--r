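# The household-firearm-ownership outcome model: design assembly, engine
# fitting, and posterior prediction over the stratum-year grid.

#' Assemble the model design from survey microdata
#'
#' Validates respondent records against the closed categorical code sets,
#' drops incomplete or invalid records (complete-case analysis) with a
#' per-reason count, and attaches the smoothed FSS covariate by
#' stratum-year.  The resulting design has one row per respondent with the
#' eight covariates (year, state, four binary demographics, survey
#' indicator, smoothed FSS) and the binary outcome.
#'
#' @param records Respondent table: `year`, `survey`, the five strata
#'   columns, `response` (0/1).
#' @param smoothed_fss A `smoothed_fss` (may be `NULL` when
#'   `include_fss = FALSE`).
#' @param frame The `strata_frame`.
#' @param years Study window; records outside it are dropped.
#' @param include_fss Attach the smoothed FSS covariate?
#' @return List of class `hfr_design`: `data` (clean design rows),
#'   `dropped` (named integer vector of drop reasons), `years`,
#'   `include_fss`, `states`.
#' @export
assemble_design <- function(records, smoothed_fss, frame,
                            years = sort(unique(records$year)),
                            include_fss = TRUE) {
  need <- c("year", "survey", .strata_fields, "response")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("microdata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (include_fss && is.null(smoothed_fss))
    stop("smoothed_fss required when include_fss = TRUE")

  dropped <- c(missing_field = 0L, unknown_code = 0L, year_out_of_window = 0L)
  ok_complete <- stats::complete.cases(records[need])
  dropped["missing_field"] <- sum(!ok_complete)
  rec <- records[ok_complete, , drop = FALSE]

  ok_code <- rec$survey %in% .survey_codes &
    rec$gender %in% .codes$gender &
    rec$marital %in% .codes$marital &
    rec$race %in% .codes$race &
    rec$urbanicity %in% .codes$urbanicity &
    !is.na(match_strata(frame, rec)) &
    rec$response %in% c(0L, 1L)
  dropped["unknown_code"] <- sum(!ok_code)
  rec <- rec[ok_code, , drop = FALSE]

  ok_year <- rec$year %in% years
  dropped["year_out_of_window"] <- sum(!ok_year)
  rec <- rec[ok_year, , drop = FALSE]

  data <- rec[need]
  if (include_fss) data$fss <- .fss_lookup(smoothed_fss, frame, rec)
  rownames(data) <- NULL
  structure(list(data = data, dropped = dropped, years = years,
                 include_fss = include_fss,
                 states = sort(unique(frame$state))),
            class = "hfr_design")
}

#' @export
print.hfr_design <- function(x, ...) {
  cat("hfr_design:", nrow(x$data), "respondents;",
      sum(x$dropped), "dropped (",
      paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Fit the household-firearm outcome model
#'
#' Binds the assembled design to an engine.  The `"bart"` engine is the
#' probit tree ensemble; its MCMC runs when predictions are first requested
#' (training and grid prediction share one chain) and the resulting draws
#' are cached on the fitted object.  The `"hierarchical"` engine fits a
#' binomial state-random-intercept GLMM immediately.
#'
#' @param design An `hfr_design` from [assemble_design()].
#' @param engine `"bart"` or `"hierarchical"`.
#' @param settings [engine_settings()].
#' @param seed Integer seed for the posterior simulation.
#' @return An `hfr_fit` object.
#' @export
fit_hfr_model <- function(design, engine = c("bart", "hierarchical"),
                          settings = engine_settings(), seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(inherits(design, "hfr_design"))
  if (nrow(design$data) == 0) stop("no usable respondent records")
  if (length(unique(design$data$response)) < 2)
    stop("constant outcome: need both response values to fit")
  fit <- new.env(parent = emptyenv())
  fit$design <- design
  fit$engine <- engine
  fit$settings <- settings
  fit$seed <- as.integer(seed)
  fit$cache <- list()
  if (engine == "hierarchical") {
    fit$hier <- .fit_hier(design$data, include_survey = TRUE,
                          include_fss = design$include_fss)
    if (any(!is.finite(unlist(lme4::fixef(fit$hier)))))
      stop("hierarchical engine produced non-finite estimates")
  }
  class(fit) <- "hfr_fit"
  fit
}

#' @export
print.hfr_fit <- function(x, ...) {
  cat("hfr_fit: engine =", x$engine, "| n =", nrow(x$design$data),
    "| ndraw =", x$settings$ndraw, "| seed =", x$seed, "\n")
  invisible(x)
}

#' Posterior stratum-year probabilities
#'
#' Predicts P(household firearm) for every stratum in the frame and every
#' requested year, with the survey indicator held at `reference_survey`
#' (the in-person level by default, a documented sensitivity knob).
#' Returns the full posterior draw array, the pipeline's central product.
#'
#' @param fit An `hfr_fit`.
#' @param frame The `strata_frame`.
#' @param years Years of the prediction grid.
#' @param smoothed_fss `smoothed_fss` covering the full grid (required when
#'   the model includes the FSS covariate).
#' @param reference_survey Survey level predictions are made at.
#' @return An `hfr_posterior`: list with `draws` (array draw x stratum x
#'   year, values strictly in (0,1)), `years`, `engine`, `seed`,
#'   `settings`, `diagnostics`.
#' @export
predict_strata_probabilities <- function(fit, frame, years,
                                         smoothed_fss = NULL,
                                         reference_survey = "in_person") {
  stopifnot(inherits(fit, "hfr_fit"))
  if (!reference_survey %in% .survey_codes)
    stop("unknown survey level: ", reference_survey)
  grid <- data.frame(frame[rep(seq_len(nrow(frame)), length(years)),
                           .strata_fields],
                     year = rep(years, each = nrow(frame)),
                     survey = reference_survey)
  if (fit$design$include_fss) {
    if (is.null(smoothed_fss))
      stop("smoothed_fss required for the prediction grid")
    grid$fss <- .fss_lookup(smoothed_fss, frame, grid)
  }
  key <- paste(reference_survey, paste(years, collapse = ","),
               nrow(frame), sep = "/")
  if (!is.null(fit$cache[[key]]))
    return(fit$cache[[key]])

  diagnostics <- list()
  if (fit$engine == "bart") {
    cells <- .binomial_cells(fit$design$data)
    X <- .design_matrix(cells, fit$design$states,
                        include_survey = TRUE,
                        include_fss = fit$design$include_fss)
    Xp <- .design_matrix(grid, fit$design$states, include_survey = TRUE,
                         include_fss = fit$design$include_fss)
    run <- .run_bart(X, cells$trials, cells$successes, Xp,
                     fit$settings, fit$seed)
    pred <- run$pred
    diagnostics <- run[c("accept_rate", "mean_leaf_depth")]
  } else {
    pred <- .predict_hier(fit$hier, grid, fit$settings$ndraw, fit$seed)
  }
  draws <- array(pred, dim = c(nrow(pred), nrow(frame), length(years)),
                 dimnames = list(NULL, NULL, years))
  post <- structure(list(draws = draws, years = years, engine = fit$engine,
                         seed = fit$seed, settings = fit$settings,
                         reference_survey = reference_survey,
                         diagnostics = diagnostics),
                    class = "hfr_posterior")
  fit$cache[[key]] <- post
  post
}

#' @export
print.hfr_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat("hfr_posterior:", d[1], "draws x", d[2], "strata x", d[3], "years;",
      "engine =", x$engine, "\n")
  invisible(x)
}
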