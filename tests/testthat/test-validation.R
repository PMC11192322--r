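# Region folds, cross-validated predictions, Brier/RMSE scoring, and
# prevalence prediction intervals.

test_that("leave-region-out folds partition the data", {
  pts <- unit_points(60, 1)
  labels <- rep(c("A", "B", "C"), each = 20)
  folds <- make_folds(pts, labels)
  expect_length(folds$folds, 3)
  tests <- lapply(folds$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:60)          # exhaustive
  expect_equal(sum(vapply(tests, length, 1L)), 60) # disjoint
  for (fd in folds$folds)
    expect_equal(sort(c(fd$train, fd$test)), 1:60)
  expect_error(make_folds(pts, rep("A", 60)), "at least 2")
  expect_error(make_folds(pts, c("A", "B")), "one region label")
})

test_that("rmse_score computes the root Brier score", {
  expect_equal(rmse_score(c(1, 0, 1, 0), c(1, 0, 1, 0)), 0)
  expect_equal(rmse_score(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(2)
  y <- rbinom(30, 1, 0.4); mu <- runif(30)
  o <- sample(30)
  expect_equal(rmse_score(y, mu), rmse_score(y[o], mu[o]))
  expect_true(rmse_score(y, mu) >= 0 && rmse_score(y, mu) <= 1)
  expect_error(rmse_score(numeric(0), numeric(0)), "empty")
  expect_error(rmse_score(c(1, 0), c(0.5)), "lengths")
  expect_error(rmse_score(c(1, 0), c(0.5, 1.4)), "0, 1")
})

test_that("cross-validated intercept-only predictions track training
           prevalence", {
  set.seed(6)
  n <- 240
  pts <- unit_points(n, 6)
  y <- rbinom(n, 1, 0.3)   # no structure at all
  sp <- species_observations(pts, y)
  labels <- ifelse(pts$x < 0.5, ifelse(pts$y < 0.5, "SW", "NW"),
                   ifelse(pts$y < 0.5, "SE", "NE"))
  folds <- make_folds(pts, labels)
  spec <- sdm_spec(spatial = FALSE, intercept = TRUE)
  cv <- cross_validate("direct", sp, list(), spec, folds,
                       inference = test_inference(), n_draws = 150)
  expect_true(all(!is.na(cv$pred$mu_mean)))        # every location predicted
  expect_equal(length(unique(cv$pred$fold[!is.na(cv$pred$fold)])), 4)
  for (fd in folds$folds) {
    train_prev <- mean(y[fd$train])
    expect_equal(mean(cv$pred$mu_mean[fd$test]), train_prev, tolerance = 0.06)
  }
})

test_that("paired fold structure scores both models on identical splits", {
  ds <- tiny_dataset(9, N = 160, M = 40)
  labels <- ifelse(ds$species$points$x < 0.5, "W", "E")
  folds <- make_folds(ds$species$points, labels)
  inf <- test_inference()
  cv_ts <- suppressWarnings(cross_validate("two_stage", ds$species, ds$abiotic,
                                           sim_spec(), folds, inference = inf,
                                           n_draws = 100))
  cv_jt <- suppressWarnings(cross_validate("joint", ds$species, ds$abiotic,
                                           sim_spec(), folds, inference = inf,
                                           n_draws = 100))
  expect_equal(cv_ts$pred$fold, cv_jt$pred$fold)
  expect_equal(cv_ts$pred$y, cv_jt$pred$y)
  r_ts <- rmse_score(cv_ts$pred$y, cv_ts$pred$mu_mean)
  r_jt <- rmse_score(cv_jt$pred$y, cv_jt$pred$mu_mean)
  expect_true(is.finite(r_ts) && is.finite(r_jt))
})

test_that("prevalence intervals: degenerate posteriors and binomial floor", {
  fake_cv <- structure(list(
    pred = data.frame(location = 1:40, region = rep(c("A", "B"), each = 20),
                      fold = 1L, y = rep(0, 40), mu_mean = rep(0, 40)),
    mu_draws = matrix(0, 40, 50), failed_regions = character(0),
    kind = "direct", hold_out_abiotic = FALSE), class = "cv_predictions")
  pi0 <- prevalence_intervals(fake_cv, n_samples = 200, seed = 1)
  expect_equal(pi0$q2.5, c(0, 0))
  expect_equal(pi0$q97.5, c(0, 0))
  expect_equal(pi0$predicted_mean, c(0, 0))
  fake_cv$mu_draws[] <- 1; fake_cv$pred$mu_mean <- 1; fake_cv$pred$y <- 1
  pi1 <- prevalence_intervals(fake_cv, n_samples = 200, seed = 1)
  expect_equal(pi1$q2.5, c(1, 1)); expect_equal(pi1$q97.5, c(1, 1))
  expect_warning(prevalence_intervals(fake_cv, n_samples = 50, seed = 1),
                 "fewer than 100")
  # width >= pure binomial width at the posterior-mean probabilities
  set.seed(4)
  mu <- runif(40, 0.2, 0.6)
  fake_cv$mu_draws <- matrix(rep(mu, 50), 40) + matrix(rnorm(2000, 0, 0.05), 40)
  fake_cv$mu_draws <- pmin(pmax(fake_cv$mu_draws, 0), 1)
  fake_cv$pred$mu_mean <- rowMeans(fake_cv$mu_draws)
  pi2 <- prevalence_intervals(fake_cv, n_samples = 400, seed = 2)
  for (r in c("A", "B")) {
    idx <- which(fake_cv$pred$region == r)
    bin <- replicate(400, mean(rbinom(20, 1, mu[idx])))
    bw <- diff(quantile(bin, c(0.025, 0.975)))
    expect_gte(pi2$q97.5[pi2$region == r] - pi2$q2.5[pi2$region == r],
               bw * 0.8)
  }
})

test_that("holding out abiotic observations by region is supported and
           reported", {
  ds <- tiny_dataset(10, N = 120, M = 40)
  labels <- ifelse(ds$species$points$x < 0.5, "W", "E")
  ab_labels <- ifelse(ds$abiotic$x1$points$x < 0.5, "W", "E")
  folds <- make_folds(ds$species$points, labels)
  cv <- suppressWarnings(cross_validate("two_stage", ds$species, ds$abiotic,
                                        sim_spec(), folds,
                                        inference = test_inference(),
                                        hold_out_abiotic = TRUE,
                                        abiotic_labels = ab_labels,
                                        n_draws = 60))
  expect_true(cv$hold_out_abiotic)
  expect_error(cross_validate("two_stage", ds$species, ds$abiotic, sim_spec(),
                              folds, inference = test_inference(),
                              hold_out_abiotic = TRUE),
               "abiotic_labels")
})
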