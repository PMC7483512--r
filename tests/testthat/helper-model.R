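# Shared fixtures: the default model is validated once; small helpers build
# reduced configurations so individual tests stay fast.

tm <- local({
  model <- NULL
  function() {
    if (is.null(model)) model <<- default_model()
    model
  }
})

# Even inoculum over all ten groups (every strain starts with biomass > 0).
even_profile <- function() {
  donor_profile(stats::setNames(rep(0.1, 10), paste0("M", 1:10)),
                label = "even")
}

# Copy of the model with every pathway's mu_max forced to zero (pure washout).
zero_growth_model <- function() {
  m <- tm()
  for (id in names(m$mfgs)) {
    for (p in names(m$mfgs[[id]]$pathways)) {
      m$mfgs[[id]]$pathways[[p]]$mu_max <- 0
    }
  }
  m
}

# Short deterministic config used by engine round-trip/determinism tests.
quick_config <- function(seed = 7L, ...) {
  scenario_config(pH = 6.5, inoculum = even_profile(), lactate_feed = 0,
                  n_runs = 2, horizon = 1, out_dt = 0.25, seed = seed, ...)
}
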