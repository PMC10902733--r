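# FSS-proxy calibration: the best linear map from the firearm-suicide
# proportion to survey-based ownership over state-years, and the systematic
# state / demographic / temporal biases that remain.

#' Fit the linear FSS proxy
#'
#' Ordinary least squares of state-year HFR on state-year raw FSS: the
#' linear transformation of FSS with the smallest squared discrepancy from
#' HFR over the fitting units.  State-years with undefined FSS (zero
#' suicides) are excluded with a logged count.
#'
#' @param fss State-year FSS table from
#'   `compute_raw_fss(suicides, by = c("state", "year"))`.
#' @param hfr State-year HFR estimates: columns `state`, `year`, `estimate`
#'   (posterior means), e.g. built from [estimate_panel()] over states.
#' @return A `proxy_calibration`: list with `intercept`, `slope`, `n`
#'   (fitting units), `correlation` (Pearson, FSS vs HFR), `n_excluded`,
#'   and `data` (per-unit `state`, `year`, `fss`, `hfr`, `proxy`,
#'   `residual = proxy - hfr`; positive residual = proxy overestimates).
#' @export
fit_linear_proxy <- function(fss, hfr) {
  need_f <- c("state", "year", "fss")
  if (!all(need_f %in% names(fss)))
    stop("fss table needs columns: ", paste(need_f, collapse = ", "))
  if (!all(c("state", "year", "estimate") %in% names(hfr)))
    stop("hfr table needs columns: state, year, estimate")
  m <- merge(fss[c("state", "year", "fss")],
             hfr[c("state", "year", "estimate")], by = c("state", "year"))
  names(m)[names(m) == "estimate"] <- "hfr"
  n_excluded <- sum(is.na(m$fss))
  if (n_excluded) message(n_excluded, " unit(s) with undefined FSS excluded")
  m <- m[!is.na(m$fss) & !is.na(m$hfr), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 units with defined FSS")
  if (var(m$fss) == 0) stop("degenerate proxy: FSS has zero variance")
  fit <- lm(hfr ~ fss, data = m)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  m$proxy <- intercept + slope * m$fss
  m$residual <- m$proxy - m$hfr
  m <- m[order(m$state, m$year), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(intercept = intercept, slope = slope, n = nrow(m),
                 correlation = stats::cor(m$fss, m$hfr),
                 n_excluded = n_excluded, data = m),
            class = "proxy_calibration")
}

#' @export
print.proxy_calibration <- function(x, ...) {
  cat(sprintf(
    "proxy_calibration: proxy = %.4f + %.4f * FSS over %d state-years (r = %.3f)\n",
    x$intercept, x$slope, x$n, x$correlation))
  invisible(x)
}

#' Mean proxy bias by state
#'
#' For each state, the mean over years of `proxy - HFR`; positive values
#' mean the FSS proxy overestimates ownership in that state.
#'
#' @param cal A `proxy_calibration`.
#' @return Data frame `state`, `n_years`, `bias`, sorted by bias.
#' @export
proxy_bias_by_state <- function(cal) {
  stopifnot(inherits(cal, "proxy_calibration"))
  agg <- aggregate(list(bias = cal$data$residual,
                        n_years = rep(1L, nrow(cal$data))),
                   by = cal$data["state"], FUN = sum)
  agg$bias <- agg$bias / agg$n_years
  agg <- agg[order(agg$bias), c("state", "n_years", "bias")]
  rownames(agg) <- NULL
  agg
}

#' Proxy bias by demographic group
#'
#' Applies the fitted calibration to group-level FSS (suicide counts summed
#' to the group) and compares with group-level poststratified HFR, per
#' group-year and averaged over years.
#'
#' @param fss_group Group-year FSS table: grouping column(s), `year`, `fss`.
#' @param hfr_group Group-year HFR table: same grouping column(s), `year`,
#'   `estimate`.
#' @param cal A `proxy_calibration`.
#' @return List: `by_group` (group, `n_years`, `bias`) and `by_group_year`
#'   (group, `year`, `fss`, `hfr`, `proxy`, `residual`); groups with FSS
#'   undefined in every year are excluded with a message.
#' @export
proxy_bias_by_group <- function(fss_group, hfr_group, cal) {
  stopifnot(inherits(cal, "proxy_calibration"))
  keys <- setdiff(intersect(names(fss_group), names(hfr_group)),
                  c("fss", "estimate", "suicides", "firearm_suicides", "defined"))
  if (!"year" %in% keys) stop("group tables must share a year column")
  gcols <- setdiff(keys, "year")
  if (!length(gcols)) stop("no grouping column shared by the two tables")
  m <- merge(fss_group[c(keys, "fss")], hfr_group[c(keys, "estimate")],
             by = keys)
  names(m)[names(m) == "estimate"] <- "hfr"
  glab <- do.call(paste, c(m[gcols], sep = "|"))
  all_na <- tapply(m$fss, glab, function(v) all(is.na(v)))
  if (any(all_na)) {
    message("group(s) with FSS undefined in all years excluded: ",
            paste(names(all_na)[all_na], collapse = ", "))
    m <- m[!glab %in% names(all_na)[all_na], , drop = FALSE]
  }
  m <- m[!is.na(m$fss), , drop = FALSE]
  m$proxy <- cal$intercept + cal$slope * m$fss
  m$residual <- m$proxy - m$hfr
  m <- m[do.call(order, m[keys]), , drop = FALSE]
  rownames(m) <- NULL
  by_group <- aggregate(list(bias = m$residual, n_years = rep(1L, nrow(m))),
                        by = m[gcols], FUN = sum)
  by_group$bias <- by_group$bias / by_group$n_years
  by_group <- by_group[do.call(order, by_group[gcols]),
                       c(gcols, "n_years", "bias")]
  rownames(by_group) <- NULL
  list(by_group = by_group, by_group_year = m)
}
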