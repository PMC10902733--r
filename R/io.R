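# Validated CSV IO and the end-to-end pipeline runner.

.check_cols <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(what, " missing column(s): ",
                         paste(miss, collapse = ", "))
  invisible(df)
}

.check_codes <- function(df, what, years = NULL, survey = FALSE) {
  for (f in names(.codes)) {
    bad <- which(!df[[f]] %in% .codes[[f]])
    if (length(bad)) stop(what, ": invalid ", f, " '", df[[f]][bad[1]],
                          "' at row ", bad[1])
  }
  if (survey) {
    bad <- which(!df$survey %in% .survey_codes)
    if (length(bad)) stop(what, ": invalid survey '", df$survey[bad[1]],
                          "' at row ", bad[1])
  }
  if (!is.null(years)) {
    bad <- which(!df$year %in% years)
    if (length(bad)) stop(what, ": year ", df$year[bad[1]],
                          " at row ", bad[1], " outside the study window")
  }
  invisible(df)
}

#' Read a population CSV
#'
#' @param path CSV with the five strata columns plus `year`, `population`.
#' @param years Optional study window for year validation.
#' @return Validated data frame.
#' @export
read_population_csv <- function(path, years = NULL) {
  if (!file.exists(path)) stop("missing input: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c(.strata_fields, "year", "population"), "population table")
  .check_codes(df, "population table", years)
  .validate_pop(df)
  df
}

#' Read a survey microdata CSV
#'
#' @param path CSV with `year`, `survey`, the five strata columns,
#'   `response`.
#' @param years Optional study window for year validation.
#' @return Validated data frame.
#' @export
read_microdata_csv <- function(path, years = NULL) {
  if (!file.exists(path)) stop("missing input: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("year", "survey", .strata_fields, "response"),
              "microdata")
  .check_codes(df, "microdata", years, survey = TRUE)
  bad <- which(!df$response %in% c(0L, 1L))
  if (length(bad)) stop("microdata: invalid response at row ", bad[1])
  df
}

#' Read a suicide-count CSV
#'
#' @param path CSV with the five strata columns plus `year`, `suicides`,
#'   `firearm_suicides`.
#' @param years Optional study window for year validation.
#' @return Validated data frame.
#' @export
read_suicide_csv <- function(path, years = NULL) {
  if (!file.exists(path)) stop("missing input: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c(.strata_fields, "year", "suicides", "firearm_suicides"),
              "suicide table")
  .check_codes(df, "suicide table", years)
  .validate_suicides(df)
  df
}

#' Pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param synth A [synth_config()] (default seeded from `seed`); set `NULL`
#'   and supply `inputs` to run on externally provided CSVs.
#' @param inputs Optional named list of CSV paths (`population`,
#'   `microdata`, `suicides`) used when `synth` is `NULL`.
#' @param years Study window.
#' @param engine Outcome-model engine, `"bart"` or `"hierarchical"`.
#' @param fss_engine FSS smoother engine, `"bart"` or `"logistic"`.
#' @param settings [engine_settings()].
#' @param reference_survey Survey level for grid predictions.
#' @param include_fss Include the smoothed-FSS covariate.
#' @param symmetric_decomposition Use average-of-endpoints weights.
#' @param weighted_variance Population-weight the variance partition.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, synth = NULL, inputs = NULL,
                            years = 1990:2018,
                            engine = c("bart", "hierarchical"),
                            fss_engine = c("bart", "logistic"),
                            settings = engine_settings(),
                            reference_survey = "in_person",
                            include_fss = TRUE,
                            symmetric_decomposition = FALSE,
                            weighted_variance = FALSE) {
  engine <- match.arg(engine); fss_engine <- match.arg(fss_engine)
  if (is.null(synth) && is.null(inputs))
    synth <- synth_config(seed = seed, years = years)
  if (!is.null(synth)) validate_synth_config(synth)
  if (!is.null(inputs)) {
    miss <- setdiff(c("population", "microdata", "suicides"), names(inputs))
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
  }
  stopifnot(length(years) >= 2, !is.unsorted(years))
  if (!reference_survey %in% .survey_codes)
    stop("unknown survey level: ", reference_survey)
  structure(list(outdir = outdir, seed = as.integer(seed), synth = synth,
                 inputs = inputs, years = years, engine = engine,
                 fss_engine = fss_engine, settings = settings,
                 reference_survey = reference_survey,
                 include_fss = include_fss,
                 symmetric_decomposition = symmetric_decomposition,
                 weighted_variance = weighted_variance),
            class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' Executes, in order: strata frame, inputs (synthetic or CSV), FSS
#' smoothing, outcome model, grid prediction, poststratified panels
#' (national and per-state), temporal and state-vs-national
#' decompositions, variance partition, and proxy calibration with state
#' and demographic bias audits.  All numeric outputs are written as CSV to
#' `config$outdir` together with a JSON manifest (seed, settings, per-stage
#' row counts, config checksum).  Reruns with an identical config
#' reproduce every output.
#'
#' @param config A [pipeline_config()].
#' @param state_metadata State metadata table (default packaged).
#' @return Invisibly, a list with the in-memory stage products and the
#'   manifest.
#' @export
run_pipeline <- function(config, state_metadata = default_state_metadata()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  frame <- build_strata_frame(state_metadata)
  years <- config$years

  if (!is.null(config$synth)) {
    truth <- generate_truth_surface(config$synth, frame)
    pop <- generate_population(config$synth, frame)
    micro <- simulate_survey_microdata(truth, pop, config$synth, frame)
    suicides <- simulate_suicide_counts(truth, pop, config$synth, frame)
  } else {
    truth <- NULL
    pop <- read_population_csv(config$inputs$population, years)
    micro <- read_microdata_csv(config$inputs$microdata, years)
    suicides <- read_suicide_csv(config$inputs$suicides, years)
  }

  smoothed <- if (config$include_fss)
    fit_fss_smoother(suicides, frame, years, engine = config$fss_engine,
                     settings = config$settings, seed = config$seed + 11L)
  else NULL

  design <- assemble_design(micro, smoothed, frame, years,
                            include_fss = config$include_fss)
  fit <- fit_hfr_model(design, engine = config$engine,
                       settings = config$settings, seed = config$seed + 22L)
  post <- predict_strata_probabilities(fit, frame, years, smoothed,
                                       config$reference_survey)

  states <- sort(unique(frame$state))
  national <- estimate_panel(post, pop, frame, list(NULL), years)
  by_state <- estimate_panel(post, pop, frame, states,
                             c(min(years), max(years)))
  decomp <- decompose_all_states(post, pop, frame, min(years), max(years),
                                 symmetric = config$symmetric_decomposition)
  svn <- do.call(rbind, lapply(states, function(s)
    decompose_state_vs_national(post, pop, frame, s, max(years))))
  surf <- posterior_mean_surface(post)
  pop_w <- if (config$weighted_variance) {
    pos <- match_strata(frame, pop); yi <- match(pop$year, years)
    w <- matrix(0, nrow(frame), length(years))
    w[cbind(pos, yi)] <- pop$population
    w
  } else NULL
  vpart <- variance_partition(surf, frame, years, weights = pop_w)

  fss_sy <- compute_raw_fss(suicides, by = c("state", "year"))
  hfr_sy <- estimate_panel(post, pop, frame, states, years)
  hfr_sy$state <- sub("^state=", "", hfr_sy$target)
  cal <- fit_linear_proxy(fss_sy, hfr_sy)
  bias_state <- proxy_bias_by_state(cal)
  fss_race <- compute_raw_fss(suicides, by = c("race", "year"))
  hfr_race <- do.call(rbind, lapply(.codes$race, function(r)
    cbind(race = r, estimate_panel(post, pop, frame,
                                   list(list(race = r)), years))))
  bias_race <- proxy_bias_by_group(fss_race, hfr_race, cal)

  outs <- list(
    national_hfr = national, state_hfr = by_state,
    decomposition = decomp, state_vs_national = svn,
    state_bias = bias_state, race_bias = bias_race$by_group,
    race_bias_year = bias_race$by_group_year,
    state_year_hfr = hfr_sy)
  paths <- list()
  for (nm in names(outs)) {
    paths[[nm]] <- file.path(config$outdir, paste0(nm, ".csv"))
    write.csv(outs[[nm]], paths[[nm]], row.names = FALSE)
  }
  vp_df <- data.frame(factor = names(vpart$contributions),
                      contribution = unname(vpart$contributions))
  vp_df <- rbind(vp_df,
                 data.frame(factor = "total_main_effects",
                            contribution = vpart$total_r2),
                 data.frame(factor = paste0("with_", names(vpart$r2_with_interactions)),
                            contribution = unname(vpart$r2_with_interactions)))
  paths$variance_partition <- file.path(config$outdir, "variance_partition.csv")
  write.csv(vp_df, paths$variance_partition, row.names = FALSE)

  cfg_json <- file.path(config$outdir, "config.json")
  cfg_ser <- config
  cfg_ser$settings <- unclass(cfg_ser$settings)
  cfg_ser$synth <- if (!is.null(cfg_ser$synth)) unclass(cfg_ser$synth)
  jsonlite::write_json(cfg_ser, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    seed = config$seed,
    engine = config$engine,
    fss_engine = config$fss_engine,
    config_md5 = unname(tools::md5sum(cfg_json)),
    package_version = as.character(utils::packageVersion("firearmMRP")),
    n_respondents = nrow(micro),
    n_dropped = as.list(design$dropped),
    n_strata = nrow(frame),
    n_years = length(years),
    n_draws = dim(post$draws)[1],
    proxy = list(intercept = cal$intercept, slope = cal$slope, n = cal$n,
                 correlation = cal$correlation),
    rows = lapply(outs, nrow),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(frame = frame, truth = truth, pop = pop,
                 microdata = micro, suicides = suicides,
                 smoothed_fss = smoothed, design = design, fit = fit,
                 posterior = post, estimates = outs,
                 variance_partition = vpart, proxy = cal,
                 manifest = manifest, paths = paths))
}
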