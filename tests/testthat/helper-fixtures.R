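# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# default 8-day cultivation at the 10-min acquisition interval
fx_sim <- function() fx_get("sim", function() {
  simulate_series(cultivation_config())
})

fx_pre <- function() fx_get("pre", function() {
  preprocess_series(fx_sim()$series)
})

fx_peak_table <- function() fx_get("peak_table", function() {
  extract_time_series(fx_pre(), default_peak_defs())
})

# state model trained on two standard cultures plus one illumination-step
# culture (the canonical training design)
fx_training <- function() fx_get("training", function() {
  simulate_training_matrix(training_configs(seed = 21))
})

fx_model <- function() fx_get("model", function() {
  fit_state_model(fx_training())
})

# preprocessed illumination-step culture (60% -> 200% after day 1)
fx_step_pre <- function() fx_get("step_pre", function() {
  preprocess_series(simulate_series(training_configs(seed = 21)[[3]])$series)
})

# scores of the default culture under the canonical training model
fx_scores <- function() fx_get("scores", function() {
  transform_scores(state_matrix(fx_pre()$matrix), fx_model())
})

fx_novel <- function() fx_get("novel", function() {
  novel_peak_flags(fx_pre(), default_peak_defs())
})

# mid-growth emission profile with every labelled peak well above the LOD
fx_full_profile <- function() {
  c(a = 30, b = 40, c = 60, d = 80, e = 50, f = 35, g = 45,
    RIP = 1000, pre_RIP = 50)
}

# a noiseless normalized spectrum built directly on a relative axis
make_nspec <- function(rel_axis, intensity, timestamp_h = 0) {
  structure(list(rel_axis = rel_axis, intensity = intensity,
                 rip_drift_time_ms = 1, timestamp_h = timestamp_h),
            class = "normalized_spectrum")
}

gauss_mix <- function(x, centers, sigmas, amps, baseline = 0) {
  y <- rep(baseline, length(x))
  for (k in seq_along(centers)) {
    y <- y + amps[k] * exp(-(x - centers[k])^2 / (2 * sigmas[k]^2))
  }
  y
}
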