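# The acceptance checks share three simulation studies (aligned with and
# without measurement error, and misaligned at full scale). They are
# computed once on first use and cached for the remaining test blocks.

study_cache <- new.env(parent = emptyenv())

acceptance_inference <- function(seed = 2024) {
  suppressWarnings(inference_config(seed = seed, map_draws = 80,
                                    optim_maxit = 60, optim_reltol = 3e-5))
}

acceptance_study <- function(which = c("aligned_clean", "aligned_noisy",
                                       "misaligned"),
                             n_runs = 20) {
  which <- match.arg(which)
  key <- paste0(which, "_", n_runs)
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  inf <- acceptance_inference()
  s <- switch(which,
    aligned_clean = suppressWarnings(run_study(
      simulation_config(n_species_locations = 300, n_abiotic_locations = 100,
                        misalignment = FALSE, measurement_error = FALSE),
      models = c("direct", "two_stage", "joint"), n_runs = n_runs,
      seed = 2035, inference = inf, map_metrics = FALSE)),
    aligned_noisy = suppressWarnings(run_study(
      simulation_config(n_species_locations = 300, n_abiotic_locations = 100,
                        misalignment = FALSE, measurement_error = TRUE),
      models = c("direct", "two_stage", "joint"), n_runs = n_runs,
      seed = 2036, inference = inf, map_metrics = FALSE)),
    misaligned = suppressWarnings(run_study(
      simulation_config(),    # N = 1000, M = 100
      models = c("two_stage", "joint"), n_runs = n_runs,
      seed = 2037, inference = inf, map_metrics = TRUE)))
  study_cache[[key]] <- s
  s
}

study_value <- function(s, model, col) s[[col]][s$model == model]
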