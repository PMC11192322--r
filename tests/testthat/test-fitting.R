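# The three estimators and their contracts: plug-in consistency, the
# aligned/noiseless limits, prediction maps, and model comparison.

test_that("direct model requires covariates at species locations", {
  ds <- tiny_dataset(1, aligned = FALSE)
  expect_error(fit_direct(ds$species, sim_spec(), test_inference()),
               "two_stage or joint")
})

test_that("two-stage with no uncertain covariates is the direct model", {
  ds <- tiny_dataset(2, aligned = TRUE)
  f1 <- suppressWarnings(fit_two_stage(ds$species, list(), sim_spec(),
                                       inference = test_inference()))
  expect_identical(f1$kind, "direct")
})

test_that("aligned noiseless data: two-stage and joint coincide with direct", {
  ds <- tiny_dataset(4, N = 250, M = 50, aligned = TRUE, noise = FALSE)
  inf <- test_inference()
  fd <- fit_direct(ds$species, sim_spec(), inf)
  ft <- suppressWarnings(fit_two_stage(ds$species, ds$abiotic, sim_spec(),
                                       inference = inf))
  fj <- suppressWarnings(fit_joint(ds$species, ds$abiotic, sim_spec(),
                                   inference = inf, stage1 = ft$stage1))
  b <- function(f) f$coefficients$mean[f$coefficients$term == "x1"]
  expect_equal(b(ft), b(fd), tolerance = 0.05)
  expect_equal(b(fj), b(fd), tolerance = 0.15)
})

test_that("a zero-variance covariate keeps its prior", {
  ds <- tiny_dataset(5, N = 150, aligned = TRUE)
  covs <- ds$species$covariates
  covs$flat <- 0
  sp <- species_observations(ds$species$points, ds$species$y, covs)
  spec <- sdm_spec(linear = c("x1", "x2", "flat"), spatial = FALSE)
  fit <- fit_direct(sp, spec, test_inference())
  row <- fit$coefficients[fit$coefficients$term == "flat", ]
  expect_equal(row$mean, 0, tolerance = 1)
  expect_equal(row$sd, sqrt(1000), tolerance = 1)
})

test_that("occurrence maps: probability bounds, draw-wise transformation,
           intercept-only constancy", {
  set.seed(31)
  n <- 40
  y <- rbinom(n, 1, 0.3)
  sp <- species_observations(unit_points(n, 31), y)
  spec <- sdm_spec(spatial = FALSE, intercept = TRUE)
  fit <- fit_direct(sp, spec, test_inference())
  grid <- unit_square_grid(4)
  maps <- predict_occurrence_map(fit, grid, n_draws = 400, seed = 99)
  # intercept-only: constant map
  expect_lt(diff(range(maps$probability$mean)), 1e-12)
  expect_true(all(maps$probability$mean > 0 & maps$probability$mean < 1))
  expect_true(all(maps$probability$sd <= 0.5 + 1e-12))
  # probability summaries are draw-wise means of logistic(eta): with a wide
  # intercept posterior E[logistic(eta)] differs from logistic(E[eta])
  d <- fit$draws(400, seed = 99 %% .Machine$integer.max)
  eta0 <- d$beta["(Intercept)", ]
  expect_equal(maps$probability$mean[1], mean(plogis(eta0)), tolerance = 0.02)
  skewed_gap <- abs(mean(plogis(eta0)) - plogis(mean(eta0)))
  expect_gt(skewed_gap, 0)   # the two summaries genuinely differ
})

test_that("map masking reports cells lacking known covariates", {
  ds <- tiny_dataset(6, N = 150, aligned = TRUE)
  fit <- fit_direct(ds$species, sim_spec(), test_inference())
  grid <- unit_square_grid(3)
  gc <- data.frame(x1 = c(NA, rnorm(8)), x2 = rnorm(9))
  maps <- predict_occurrence_map(fit, grid, grid_covariates = gc,
                                 n_draws = 30, seed = 2)
  expect_equal(maps$n_masked, 1)
  expect_true(is.na(maps$probability$mean[1]))
  expect_error(predict_occurrence_map(fit, grid), "no interpolation")
})

test_that("compare_models handles identical, negated and constant maps", {
  ds <- tiny_dataset(7, N = 150, aligned = TRUE)
  inf <- test_inference()
  fit <- fit_direct(ds$species, sim_spec(), inf)
  grid <- unit_square_grid(4)
  gcov <- data.frame(x1 = rnorm(16), x2 = rnorm(16))
  maps <- predict_occurrence_map(fit, grid, grid_covariates = gcov,
                                 n_draws = 50, seed = 3)
  cmp <- compare_models(fit, fit, maps, maps)
  expect_equal(cmp$coefficient_correlation, 1)
  expect_true(all(cmp$map_correlations == 1))
  neg <- maps; neg$log_odds$mean <- -maps$log_odds$mean
  cmp2 <- compare_models(fit, fit, maps, neg)
  expect_equal(unname(cmp2$map_correlations["log_odds"]), -1)
  const <- maps; const$probability$mean[] <- 0.2
  cmp3 <- compare_models(fit, fit, maps, const)
  expect_true(is.na(cmp3$map_correlations["probability"]))
  expect_match(paste(cmp3$notes, collapse = " "), "undefined")
  other <- predict_occurrence_map(fit, unit_square_grid(5),
                                  grid_covariates = data.frame(x1 = rnorm(25),
                                                               x2 = rnorm(25)),
                                  n_draws = 20, seed = 4)
  expect_error(compare_models(fit, fit, maps, other), "different grids")
})

test_that("full-feedback joint fit runs and agrees with the modular joint
           fit on a small instance", {
  ds <- tiny_dataset(8, N = 120, M = 30)
  inf_lat <- test_inference()
  fj <- suppressWarnings(fit_joint(ds$species, ds$abiotic, sim_spec(),
                                   inference = inf_lat))
  inf_full <- suppressWarnings(
    inference_config(seed = 1, n_draws = 400, map_draws = 60,
                     optim_maxit = 60, feedback = "full"))
  fjf <- suppressWarnings(fit_joint(ds$species, ds$abiotic, sim_spec(),
                                    inference = inf_full,
                                    stage1 = fj$stage1))
  expect_true(isTRUE(fjf$diagnostics$full_feedback))
  b <- function(f) f$coefficients$mean[f$coefficients$term == "x1"]
  expect_equal(b(fjf), b(fj), tolerance = 0.5)
})

test_that("attenuation oracle: identity at zero noise, closed form,
           total attenuation limit", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(attenuation_oracle(S, 0, c(1, 1)), c(1, 1))
  # hand algebra: (S + 0.3 I)^-1 S (1,1)' = (5/6, 5/6)
  expect_equal(attenuation_oracle(S, 0.3, c(1, 1)), c(5, 5) / 6,
               tolerance = 1e-10)
  expect_equal(attenuation_oracle(S, 1e8, c(1, 1)), c(0, 0), tolerance = 1e-6)
  expect_error(attenuation_oracle(matrix(c(1, 1, 1, 1), 2), 0.1, c(1, 1)),
               "positive definite")
})
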