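# Structural analyses of the estimate surface: temporal rate-vs-composition
# (Kitagawa-style) decomposition, state-vs-national cross-sectional
# decomposition, and an LMG variance partition over factor groups.

#' Decompose HFR change into rate and composition components
#'
#' Splits the change in a unit's poststratified HFR between two years into
#' (1) a rate component: the change expected had population composition
#' stayed at its `year0` value, and (2) a composition component: the
#' remainder, attributable to shifts in the population mix.  With stratum
#' rates `p_s(t)` and weights `w_s(t)`:
#' `total = sum(w1 p1) - sum(w0 p0)`, `rate = sum(w0 (p1 - p0))`,
#' `composition = total - rate`.  The symmetric variant averages the
#' endpoint weightings instead of anchoring at `year0`.
#'
#' @param post An `hfr_posterior`.
#' @param pop Population table.
#' @param frame The `strata_frame`.
#' @param unit Named-list selector for the unit (e.g. `list(state = "MT")`),
#'   `NULL` for the nation.
#' @param year0,year1 Endpoint years.
#' @param symmetric Use the average-of-endpoints weighting.
#' @param draws Also decompose each posterior draw and attach equal-tailed
#'   95% intervals for the components.
#' @return A `decomposition` data frame row: `unit`, `year0`, `year1`,
#'   `total`, `rate_component`, `composition_component`,
#'   `composition_share` (NA when `total` is 0), plus interval columns when
#'   `draws = TRUE`.
#' @export
decompose_temporal <- function(post, pop, frame, unit = NULL, year0, year1,
                               symmetric = FALSE, draws = FALSE) {
  w0 <- compute_weights(pop, frame, unit, year0)
  w1 <- compute_weights(pop, frame, unit, year1)
  i0 <- match(year0, post$years); i1 <- match(year1, post$years)
  if (is.na(i0) || is.na(i1)) stop("decomposition years not in posterior grid")
  surf <- posterior_mean_surface(post)
  comp3 <- function(p0, p1) {
    total <- sum(w1 * p1) - sum(w0 * p0)
    wr <- if (symmetric) (w0 + w1) / 2 else w0
    rate <- sum(wr * (p1 - p0))
    c(total = total, rate = rate, composition = total - rate)
  }
  cc <- comp3(surf[, i0], surf[, i1])
  out <- data.frame(unit = .target_label(unit), year0 = year0, year1 = year1,
                    total = cc["total"], rate_component = cc["rate"],
                    composition_component = cc["composition"],
                    composition_share =
                      if (cc["total"] != 0) cc["composition"] / cc["total"]
                      else NA_real_,
                    row.names = NULL)
  if (draws) {
    per <- t(vapply(seq_len(dim(post$draws)[1]), function(d)
      comp3(post$draws[d, , i0], post$draws[d, , i1]), numeric(3)))
    qs <- apply(per, 2, quantile, c(0.025, 0.975))
    out$total_lower <- qs[1, "total"];        out$total_upper <- qs[2, "total"]
    out$rate_lower <- qs[1, "rate"];          out$rate_upper <- qs[2, "rate"]
    out$composition_lower <- qs[1, "composition"]
    out$composition_upper <- qs[2, "composition"]
    out$draw_means <- I(list(colMeans(per)))
  }
  class(out) <- c("decomposition", "data.frame")
  out
}

#' Temporal decomposition for every state
#'
#' @inheritParams decompose_temporal
#' @return A `decomposition` data frame with one row per state, sorted by
#'   state code.
#' @export
decompose_all_states <- function(post, pop, frame, year0, year1,
                                 symmetric = FALSE) {
  states <- sort(unique(frame$state))
  out <- do.call(rbind, lapply(states, function(s)
    decompose_temporal(post, pop, frame, list(state = s), year0, year1,
                       symmetric = symmetric)))
  rownames(out) <- NULL
  out
}

#' Decompose a state-vs-national HFR difference
#'
#' Splits the gap between a state's HFR and the national HFR in one year
#' into a composition part (the state's demographic mix applied to national
#' demographic-cell rates) and a rate part (the state's own rate deviations
#' under its own mix), over the 16 shared demographic cells
#' (gender x marital x race x urbanicity):
#' `difference = sum(w_c^state p_c^state) - sum(w_c^US p_c^US)`,
#' `composition = sum((w_c^state - w_c^US) p_c^US)`,
#' `rate = difference - composition`.
#'
#' @inheritParams decompose_temporal
#' @param state State code.
#' @param year Year of comparison.
#' @return A `decomposition` data frame row with `total` (state minus
#'   national), `rate_component`, `composition_component`,
#'   `composition_share`.
#' @export
decompose_state_vs_national <- function(post, pop, frame, state, year) {
  yi <- match(year, post$years)
  if (is.na(yi)) stop("year ", year, " not in the posterior grid")
  surf <- posterior_mean_surface(post)[, yi]
  py <- pop[pop$year == year, , drop = FALSE]
  pos <- match_strata(frame, py)
  cnt <- numeric(nrow(frame)); cnt[pos] <- py$population
  in_state <- frame$state == state
  if (sum(cnt[in_state]) <= 0) stop("empty target population")
  cell <- interaction(frame$gender, frame$marital, frame$race,
                      frame$urbanicity, drop = FALSE)
  pop_cell_us <- tapply(cnt, cell, sum)
  pop_cell_st <- tapply(cnt * in_state, cell, sum)
  rate_cell_us <- tapply(cnt * surf, cell, sum) / pop_cell_us
  rate_cell_st <- ifelse(pop_cell_st > 0,
                         tapply(cnt * surf * in_state, cell, sum) /
                           pmax(pop_cell_st, 1e-300), NA_real_)
  w_us <- pop_cell_us / sum(pop_cell_us)
  w_st <- pop_cell_st / sum(pop_cell_st)
  # cells absent from the state (e.g. urban cells of an urban-free state)
  # carry zero state weight; their national rate is still defined
  rate_cell_st[w_st == 0] <- 0
  difference <- sum(w_st * rate_cell_st) - sum(w_us * rate_cell_us)
  composition <- sum((w_st - w_us) * rate_cell_us)
  rate <- difference - composition
  out <- data.frame(unit = state, year = year, total = difference,
                    rate_component = rate, composition_component = composition,
                    composition_share =
                      if (difference != 0) composition / difference
                      else NA_real_,
                    row.names = NULL)
  class(out) <- c("decomposition", "data.frame")
  out
}

#' Variance partition of the estimate surface
#'
#' Fits linear models of posterior-mean stratum-year estimates on the six
#' factor groups (state, race, gender, marital status, urbanicity, year)
#' and attributes the main-effects R-squared to factors by LMG/Shapley
#' averaging of the marginal R-squared gain over all orderings of the
#' groups.  Optionally reports the R-squared after adding interaction
#' terms (default: gender x marital).
#'
#' @param surface Matrix strata x years of estimates (e.g.
#'   [posterior_mean_surface()]).
#' @param frame The `strata_frame`.
#' @param years Years matching the surface columns.
#' @param interactions List of character pairs to add, default
#'   `list(c("gender", "marital"))`.
#' @param weights Optional nonnegative cell weights (strata x years matrix,
#'   e.g. population), for a population-weighted partition; default
#'   unweighted.
#' @return A `variance_partition`: list with `total_r2`, `contributions`
#'   (named, summing to `total_r2`), `r2_with_interactions`, and the
#'   per-subset R-squared table.
#' @export
variance_partition <- function(surface, frame, years,
                               interactions = list(c("gender", "marital")),
                               weights = NULL) {
  stopifnot(ncol(surface) == length(years), nrow(surface) == nrow(frame))
  dat <- data.frame(
    est = as.vector(surface),
    state = factor(rep(frame$state, length(years))),
    race = factor(rep(frame$race, length(years))),
    gender = factor(rep(frame$gender, length(years))),
    marital = factor(rep(frame$marital, length(years))),
    urbanicity = factor(rep(frame$urbanicity, length(years))),
    year = factor(rep(years, each = nrow(frame))))
  w <- if (is.null(weights)) NULL else as.vector(weights)

  groups <- c("state", "race", "gender", "marital", "urbanicity", "year")
  degenerate <- groups[vapply(groups, function(g)
    nlevels(droplevels(dat[[g]])) < 2, logical(1))]
  if (length(degenerate)) {
    warning("dropping degenerate factor(s): ",
            paste(degenerate, collapse = ", "))
    groups <- setdiff(groups, degenerate)
  }
  K <- length(groups)

  r2_of <- function(rhs) {
    if (!length(rhs)) return(0)
    f <- as.formula(paste("est ~", paste(rhs, collapse = " + ")))
    fit <- if (is.null(w)) lm(f, data = dat) else lm(f, data = dat, weights = w)
    ww <- if (is.null(w)) rep(1, nrow(dat)) else w
    ybar <- sum(ww * dat$est) / sum(ww)
    sst <- sum(ww * (dat$est - ybar)^2)
    if (sst == 0) return(0)
    1 - sum(ww * stats::residuals(fit)^2) / sst
  }

  subsets <- lapply(0:(2^K - 1), function(m) groups[bitwAnd(m, 2^(0:(K - 1))) > 0])
  skey <- function(s) if (!length(s)) "(none)" else paste(sort(s), collapse = "+")
  r2 <- vapply(subsets, r2_of, numeric(1))
  names(r2) <- vapply(subsets, skey, "")

  contrib <- setNames(numeric(K), groups)
  for (f in groups) {
    for (S in subsets) {
      if (f %in% S) next
      s <- length(S)
      wgt <- factorial(s) * factorial(K - s - 1) / factorial(K)
      contrib[f] <- contrib[f] + wgt * (r2[[skey(c(S, f))]] - r2[[skey(S)]])
    }
  }

  r2_int <- vapply(interactions, function(pr) {
    pr <- intersect(pr, groups)
    rhs <- c(groups, if (length(pr) == 2) paste(pr, collapse = ":"))
    r2_of(rhs)
  }, numeric(1))
  names(r2_int) <- vapply(interactions, paste, "", collapse = ":")

  structure(list(total_r2 = r2[[length(r2)]], contributions = contrib,
                 r2_with_interactions = r2_int, subset_r2 = r2,
                 groups = groups),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance_partition: main-effects R^2 =", round(x$total_r2, 4), "\n")
  print(round(sort(x$contributions, decreasing = TRUE), 4))
  if (length(x$r2_with_interactions))
    cat("with interactions:",
        paste(names(x$r2_with_interactions),
              round(x$r2_with_interactions, 4), sep = " = ",
              collapse = "; "), "\n")
  invisible(x)
}
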