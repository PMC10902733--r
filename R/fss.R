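# Firearm-suicide proportion (FSS): the raw count ratio and the smoothed
# model-based surface used as a covariate in the ownership model.

.validate_suicides <- function(suicides) {
  need <- c(.strata_fields, "year", "suicides", "firearm_suicides")
  miss <- setdiff(need, names(suicides))
  if (length(miss)) stop("suicide table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(suicides$firearm_suicides > suicides$suicides |
                 suicides$suicides < 0 | suicides$firearm_suicides < 0)
  if (length(bad)) stop("invalid suicide counts at row ", bad[1],
                        " (firearm suicides must be 0..total)")
  invisible(suicides)
}

#' Raw firearm-suicide proportion
#'
#' Computes the fraction of suicides committed with a firearm, first summing
#' counts over the requested aggregation unit and then dividing (a ratio of
#' sums, not a mean of ratios).  Units with zero suicides get `NA` and
#' `defined = FALSE` rather than a value.
#'
#' @param suicides Suicide table (five strata columns, `year`, `suicides`,
#'   `firearm_suicides`).
#' @param by Character vector of grouping columns, e.g. `c("state", "year")`
#'   for the state-year table used in proxy calibration.  Defaults to the
#'   full stratum-year resolution.
#' @return Data frame with the grouping columns, summed `suicides` and
#'   `firearm_suicides`, `fss` (NA where undefined) and `defined`.
#' @export
compute_raw_fss <- function(suicides, by = c(.strata_fields, "year")) {
  .validate_suicides(suicides)
  miss <- setdiff(by, names(suicides))
  if (length(miss)) stop("unknown grouping column(s): ",
                         paste(miss, collapse = ", "))
  agg <- aggregate(suicides[c("suicides", "firearm_suicides")],
                   by = suicides[by], FUN = sum)
  agg <- agg[do.call(order, agg[by]), , drop = FALSE]
  rownames(agg) <- NULL
  agg$fss <- ifelse(agg$suicides > 0, agg$firearm_suicides / agg$suicides, NA_real_)
  agg$defined <- agg$suicides > 0
  agg
}

#' Fit the FSS smoothing model
#'
#' Models the probability that a suicide used a firearm as a function of
#' year, state and the four demographic fields, and predicts it for every
#' stratum-year, including cells with zero observed suicides (which borrow
#' strength from similar strata).  The default engine is the probit tree
#' ensemble fitted on one record per suicide; the `"logistic"` engine is a
#' fast binomial GLM with a natural spline in year.
#'
#' @param suicides Suicide table.
#' @param frame A `strata_frame`.
#' @param years Years to predict (default: the years present in the table).
#' @param engine `"bart"` or `"logistic"`.
#' @param settings [engine_settings()] for the tree engine.
#' @param seed Integer seed.
#' @return A `smoothed_fss` object: list with `values` (strata x years
#'   matrix strictly inside (0,1)), `years`, `engine`, and for the tree
#'   engine equal-tailed 95% bands `lower`/`upper`.
#' @export
fit_fss_smoother <- function(suicides, frame, years = NULL,
                             engine = c("bart", "logistic"),
                             settings = engine_settings(), seed = 1L) {
  engine <- match.arg(engine)
  .validate_suicides(suicides)
  if (is.null(years)) years <- sort(unique(suicides$year))
  if (sum(suicides$suicides) == 0) stop("no events to fit")
  pos <- match_strata(frame, suicides)
  if (anyNA(pos)) stop("suicide row ", which(is.na(pos))[1],
                       " does not map to a stratum in the frame")
  states <- sort(unique(frame$state))
  grid <- data.frame(frame[rep(seq_len(nrow(frame)), length(years)),
                           .strata_fields],
                     year = rep(years, each = nrow(frame)))

  if (engine == "bart") {
    cell <- suicides[suicides$suicides > 0, , drop = FALSE]
    X <- .design_matrix(cell, states, include_survey = FALSE,
                        include_fss = FALSE)
    Xp <- .design_matrix(grid, states, include_survey = FALSE,
                         include_fss = FALSE)
    run <- .run_bart(X, cell$suicides, cell$firearm_suicides, Xp,
                     settings, seed)
    vals <- matrix(colMeans(run$pred), nrow(frame), length(years))
    lo <- matrix(apply(run$pred, 2, quantile, 0.025), nrow(frame), length(years))
    hi <- matrix(apply(run$pred, 2, quantile, 0.975), nrow(frame), length(years))
  } else {
    dat <- .as_model_factors(suicides)
    df_year <- min(4L, max(1L, length(unique(dat$year)) - 1L))
    form <- cbind(firearm_suicides, suicides - firearm_suicides) ~
      splines::ns(year, df = df_year) + state + gender + marital + race +
      urbanicity
    fit <- stats::glm(form, family = stats::binomial(),
                      data = dat[dat$suicides > 0, , drop = FALSE])
    vals <- matrix(clamp01(predict(fit, newdata = .as_model_factors(grid),
                                   type = "response")),
                   nrow(frame), length(years))
    lo <- hi <- NULL
  }
  dimnames(vals) <- list(NULL, years)
  structure(list(values = clamp01(vals), lower = lo, upper = hi,
                 years = years, engine = engine, seed = seed),
            class = "smoothed_fss")
}

#' @export
print.smoothed_fss <- function(x, ...) {
  cat("smoothed_fss:", nrow(x$values), "strata x", length(x$years),
      "years; engine =", x$engine, "\n")
  cat("  value range:", sprintf("%.3f-%.3f", min(x$values), max(x$values)), "\n")
  invisible(x)
}

#' Tabulate a smoothed FSS surface
#'
#' @param x A `smoothed_fss`.
#' @param frame The `strata_frame` the surface was fitted over.
#' @param ... Unused.
#' @return Data frame: five strata columns, `year`, `estimate`, and
#'   `lower`/`upper` when the engine provides them.
#' @export
smoothed_fss_table <- function(x, frame, ...) {
  out <- data.frame(frame[rep(seq_len(nrow(frame)), length(x$years)),
                          .strata_fields],
                    year = rep(x$years, each = nrow(frame)),
                    estimate = as.vector(x$values))
  if (!is.null(x$lower)) {
    out$lower <- as.vector(x$lower)
    out$upper <- as.vector(x$upper)
  }
  rownames(out) <- NULL
  out
}

# smoothed value lookup for respondent rows
.fss_lookup <- function(smoothed, frame, df) {
  pos <- match_strata(frame, df)
  yi <- match(df$year, smoothed$years)
  if (anyNA(pos) || anyNA(yi)) {
    bad <- which(is.na(pos) | is.na(yi))[1]
    stop("no smoothed FSS value for stratum-year: ",
         strata_key(df[bad, , drop = FALSE]), " year ", df$year[bad])
  }
  smoothed$values[cbind(pos, yi)]
}
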