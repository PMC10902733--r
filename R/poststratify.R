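# Poststratification: collapse posterior stratum-year probabilities into
# population estimates with equal-tailed credible intervals.

#' Poststratified estimate for one target and year
#'
#' For each posterior draw, forms the population-weighted mean of stratum
#' probabilities over the target selection, with weights proportional to
#' stratum population in the estimate year; the point estimate is the
#' posterior mean and the interval the equal-tailed 2.5/97.5 percentiles
#' of the weighted draws.
#'
#' @param post An `hfr_posterior`.
#' @param pop Population table.
#' @param frame The `strata_frame`.
#' @param target Named-list selector as in [compute_weights()]; `NULL` =
#'   national.
#' @param year Estimate year (also the weight year).
#' @param level Credibility level (default 0.95).
#' @return One-row data frame: `target`, `year`, `estimate`, `lower`,
#'   `upper`.
#' @export
poststratify <- function(post, pop, frame, target = NULL, year,
                         level = 0.95) {
  yi <- match(year, post$years)
  if (is.na(yi)) stop("year ", year, " not in the posterior grid")
  w <- compute_weights(pop, frame, target, year)
  draws <- post$draws[, , yi, drop = FALSE][, , 1] %*% w
  a <- (1 - level) / 2
  qs <- quantile(draws, c(a, 1 - a), names = FALSE)
  data.frame(target = .target_label(target), year = year,
             estimate = mean(draws), lower = qs[1], upper = qs[2])
}

#' Per-draw poststratified series
#'
#' The weighted-sum draws themselves (no summarisation), for analyses that
#' propagate posterior uncertainty, e.g. per-draw decompositions.
#'
#' @inheritParams poststratify
#' @return Numeric vector of length ndraw.
#' @export
poststratify_draws <- function(post, pop, frame, target = NULL, year) {
  yi <- match(year, post$years)
  if (is.na(yi)) stop("year ", year, " not in the posterior grid")
  w <- compute_weights(pop, frame, target, year)
  as.vector(post$draws[, , yi, drop = FALSE][, , 1] %*% w)
}

.target_label <- function(target) {
  if (is.null(target)) return("national")
  paste(names(target), vapply(target, paste, "", collapse = "+"),
        sep = "=", collapse = ",")
}

#' Batch estimates over margins and years
#'
#' Applies [poststratify()] over a list of targets and a vector of years,
#' returning a deterministically sorted table.
#'
#' @inheritParams poststratify
#' @param targets List of named-list selectors (use `list(NULL)` for a
#'   national row); a bare character vector of state codes is also accepted.
#' @param years Years to estimate.
#' @return Data frame with one row per target x year: `target`, `year`,
#'   `estimate`, `lower`, `upper`.
#' @export
estimate_panel <- function(post, pop, frame, targets, years, level = 0.95) {
  if (is.character(targets))
    targets <- lapply(targets, function(s) list(state = s))
  rows <- lapply(targets, function(tg)
    do.call(rbind, lapply(years, function(y)
      poststratify(post, pop, frame, tg, y, level))))
  out <- do.call(rbind, rows)
  out <- out[order(out$target, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Posterior-mean stratum-year surface
#'
#' @param post An `hfr_posterior`.
#' @return Matrix strata x years of posterior means.
#' @export
posterior_mean_surface <- function(post) {
  apply(post$draws, c(2, 3), mean)
}
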