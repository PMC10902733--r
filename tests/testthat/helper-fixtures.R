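# Shared fixtures.  Expensive products (the default-configuration study run
# used by the end-to-end checks) are computed once per session and cached.

tiny_metadata <- function(n_states = 4, urban_free = 1) {
  codes <- c("AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "FL", "GA")
  data.frame(state_code = codes[seq_len(n_states)],
             has_urban_county = rep(c(1L, 0L),
                                    c(n_states - urban_free, urban_free)))
}

# a hand-built posterior over an arbitrary frame: draws can be degenerate
# (identical across draws) or supplied explicitly
fake_posterior <- function(frame, years, p = NULL, ndraw = 4, noise = 0) {
  ns <- nrow(frame)
  if (is.null(p)) p <- matrix(0.3, ns, length(years))
  draws <- array(rep(p, each = ndraw), c(ndraw, ns, length(years)))
  if (noise > 0) {
    set.seed(99)
    draws <- firearmMRP:::clamp01(draws + array(rnorm(length(draws), 0, noise),
                                                dim(draws)))
  }
  structure(list(draws = draws, years = years, engine = "fixture",
                 seed = 0L, settings = NULL, diagnostics = list()),
            class = "hfr_posterior")
}

uniform_population <- function(frame, years, count = 1000) {
  data.frame(frame[rep(seq_len(nrow(frame)), length(years)),
                   firearmMRP:::.strata_fields],
             year = rep(years, each = nrow(frame)),
             population = count, row.names = NULL)
}

# The default-configuration synthetic study: generator defaults, tree-ensemble
# engines at their default (desk) settings, fixed seed.  Cached for the
# session; several end-to-end tests read from it.
default_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synth_config(seed = 1L)
    frame <- build_strata_frame()
    truth <- generate_truth_surface(cfg, frame)
    pop <- generate_population(cfg, frame)
    micro <- simulate_survey_microdata(truth, pop, cfg, frame)
    suicides <- simulate_suicide_counts(truth, pop, cfg, frame)
    smoothed <- fit_fss_smoother(suicides, frame, cfg$years, engine = "bart",
                                 settings = engine_settings(), seed = 11L)
    design <- assemble_design(micro, smoothed, frame, cfg$years)
    fit <- fit_hfr_model(design, "bart", engine_settings(), seed = 22L)
    post <- predict_strata_probabilities(fit, frame, cfg$years, smoothed)
    cache <<- list(cfg = cfg, frame = frame, truth = truth, pop = pop,
                   micro = micro, suicides = suicides, smoothed = smoothed,
                   design = design, fit = fit, post = post)
    cache
  }
})
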