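# Shared helpers: small deterministic inputs built in code.

unit_points <- function(n, seed = 1) {
  set.seed(seed)
  points_df(runif(n), runif(n))
}

# fast inference settings for tests (still hits the full code path)
test_inference <- function(seed = 1) {
  suppressWarnings(inference_config(seed = seed, n_draws = 400,
                                    map_draws = 60, optim_maxit = 60))
}

# a small synthetic data set shared across fitting tests
tiny_dataset <- function(seed = 3, N = 200, M = 40, aligned = FALSE,
                         noise = TRUE) {
  cfg <- simulation_config(n_species_locations = N, n_abiotic_locations = M,
                           misalignment = !aligned, measurement_error = noise,
                           grid_res = 10)
  generate_dataset(cfg, seed)
}

sim_spec <- function() sdm_spec(linear = c("x1", "x2"), spatial = TRUE)
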