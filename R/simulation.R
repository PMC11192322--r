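# Ground-truth simulation study: synthetic data sets with spatially
# misaligned, error-contaminated covariates, and a study runner that scores
# the direct / two-stage / joint estimators against the known truth.

#' Configuration of the ground-truth simulation
#'
#' Defaults reproduce the reference study conditions: N = 1000 species
#' locations and M = 100 abiotic measurement locations sampled uniformly on
#' the unit square; two confounded covariates built from Matern GRFs with
#' variance 0.5 and range 0.3 (so each covariate has variance 1 and their
#' covariance is 0.5); classical measurement error of variance 0.3; linear
#' effects (beta0, beta1, beta2) = (-2, 1, 1); and a spatial residual W drawn
#' from the same Matern law. With `misalignment = FALSE` the abiotic
#' variables are also measured at all N species locations plus M extra points
#' (M + N observations in total); with `measurement_error = FALSE` the
#' observed values equal the latent values exactly.
#'
#' @param n_species_locations N (default 1000).
#' @param n_abiotic_locations M (default 100): abiotic-only locations.
#' @param grf_variance,grf_range Matern parameters of the component fields.
#' @param noise_variance measurement-error variance delta^2 (default 0.3).
#' @param betas numeric length 3: intercept and the two linear effects.
#' @param misalignment logical; if FALSE, abiotic values are observed at the
#'   species locations too.
#' @param measurement_error logical; if FALSE, delta^2 is treated as 0.
#' @param grid_res evaluation-grid resolution (cells per side, default 25).
#' @param n_runs default number of replicate data sets for [run_study()].
#' @param seed master seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_species_locations = 1000L,
                              n_abiotic_locations = 100L,
                              grf_variance = 0.5, grf_range = 0.3,
                              noise_variance = 0.3,
                              betas = c(-2, 1, 1),
                              misalignment = TRUE,
                              measurement_error = TRUE,
                              grid_res = 25L, n_runs = 30L, seed = 1L) {
  stopifnot(n_species_locations >= 1, n_abiotic_locations >= 1,
            grf_variance > 0, grf_range > 0, noise_variance >= 0,
            length(betas) == 3)
  structure(list(n_species_locations = as.integer(n_species_locations),
                 n_abiotic_locations = as.integer(n_abiotic_locations),
                 grf_variance = grf_variance, grf_range = grf_range,
                 noise_variance = noise_variance, betas = as.numeric(betas),
                 misalignment = isTRUE(misalignment),
                 measurement_error = isTRUE(measurement_error),
                 grid_res = as.integer(grid_res),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate one synthetic data set from the ground truth
#'
#' Draws Z, Z1, Z2, W ~ MVN(0, Matern(grf_variance, grf_range)) on the union
#' of all needed locations, forms the confounded covariates X1 = Z + Z1 and
#' X2 = Z + Z2, contaminates the observed values with independent N(0,
#' delta^2) measurement error, and samples species presence/absence from
#' Bernoulli(logistic(beta0 + beta1 X1 + beta2 X2 + W)).
#'
#' The returned object separates what an analyst would see (`species`,
#' `abiotic`) from the `truth` element (latent fields, eta, mu on the species
#' locations and the evaluation grid), which exists for scoring only and must
#' never be passed to a fitter.
#'
#' @param config a [simulation_config()].
#' @param run_seed integer seed for this replicate.
#' @return Object of class `synthetic_dataset` with elements `species`
#'   (a [species_observations()]; covariate columns only when aligned),
#'   `abiotic` (named list of noisy `field_realization`s), `truth`, `config`.
#' @export
generate_dataset <- function(config, run_seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  N <- config$n_species_locations; M <- config$n_abiotic_locations
  grid <- unit_square_grid(config$grid_res)
  gctr <- grid_centres(grid)
  with_seed(run_seed, {
    sp <- points_df(stats::runif(N), stats::runif(N))
    extra <- points_df(stats::runif(M), stats::runif(M))
    all_pts <- points_df(c(sp$x, extra$x, gctr$x), c(sp$y, extra$y, gctr$y))
    # misaligned: abiotic rows are the M extra points only; aligned: the
    # species locations plus the M extra points (the "M + N" setting)
    ab_rows <- if (config$misalignment) N + seq_len(M) else seq_len(N + M)
    sp_rows <- seq_len(N)
    g_rows <- N + M + seq_len(nrow(gctr))
    pars <- matern_params(config$grf_variance, config$grf_range)
    L <- chol_cov(matern_covariance_matrix(all_pts, pars),
                  scale = config$grf_variance)
    zz <- crossprod(L, matrix(stats::rnorm(nrow(all_pts) * 4), nrow(all_pts)))
    X1 <- zz[, 1] + zz[, 2]
    X2 <- zz[, 1] + zz[, 3]
    W <- zz[, 4]
    d2 <- if (config$measurement_error) config$noise_variance else 0
    x1_obs <- X1[ab_rows] + stats::rnorm(length(ab_rows), 0, sqrt(d2))
    x2_obs <- X2[ab_rows] + stats::rnorm(length(ab_rows), 0, sqrt(d2))
    b <- config$betas
    eta_sp <- b[1] + b[2] * X1[sp_rows] + b[3] * X2[sp_rows] + W[sp_rows]
    mu_sp <- stats::plogis(eta_sp)
    y <- stats::rbinom(N, 1, mu_sp)
    covs <- NULL
    if (!config$misalignment) {
      # aligned: the species rows coincide with the first N abiotic rows and
      # share the same noisy measurement
      covs <- data.frame(x1 = x1_obs[seq_len(N)], x2 = x2_obs[seq_len(N)])
    }
    ab_pts <- points_df(all_pts$x[ab_rows], all_pts$y[ab_rows])
    eta_g <- b[1] + b[2] * X1[g_rows] + b[3] * X2[g_rows] + W[g_rows]
    structure(list(
      species = species_observations(sp, y, covariates = covs),
      abiotic = list(x1 = field_realization(ab_pts, x1_obs, run_seed),
                     x2 = field_realization(ab_pts, x2_obs, run_seed)),
      truth = list(grid = grid,
                   X1_grid = X1[g_rows], X2_grid = X2[g_rows],
                   W_grid = W[g_rows], eta_grid = eta_g,
                   mu_grid = stats::plogis(eta_g),
                   X1_abiotic = X1[ab_rows], X2_abiotic = X2[ab_rows],
                   X1_species = X1[sp_rows], X2_species = X2[sp_rows],
                   W_species = W[sp_rows], eta_species = eta_sp,
                   mu_species = mu_sp, betas = b),
      config = config, run_seed = run_seed), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: N = %d species visits ",
                     "(prevalence %.3f), %d abiotic rows, %s, %s\n"),
              length(x$species$y), mean(x$species$y),
              nrow(x$abiotic$x1$points),
              if (x$config$misalignment) "misaligned" else "aligned",
              if (x$config$measurement_error) "with measurement error"
              else "noise-free"))
  invisible(x)
}

# the model spec matching the generative model: two linear covariates plus a
# spatial residual (no splines)
simulation_sdm_spec <- function(priors = prior_config()) {
  sdm_spec(linear = c("x1", "x2"), spatial = TRUE, priors = priors)
}

#' Run the simulation study and tabulate estimator performance
#'
#' For each configuration and replicate, generates a data set, fits the
#' requested models (the direct model is skipped under misalignment, where
#' covariates are unobserved at the species locations), and scores:
#' the posterior mean and sd of beta1, the squared error of the beta1
#' estimate, and (optionally) RMSEs of the predicted occurrence-probability
#' map against the true mu and of the predicted X1 map against the true X1
#' on the evaluation grid. Results are averaged over replicates.
#'
#' @param configs a [simulation_config()] or list of them.
#' @param models subset of c("direct", "two_stage", "joint").
#' @param n_runs replicates per configuration (default from the config).
#' @param seed master seed; every replicate's seed derives from it.
#' @param inference an [inference_config()].
#' @param map_metrics logical; compute the per-run prediction-map RMSEs
#'   (adds the cost of map prediction per fitted model).
#' @param map_models models for which maps are scored when `map_metrics` is
#'   TRUE (default: every fitted model except direct, which cannot map).
#' @param progress logical; print one line per completed run.
#' @return A data frame (class `study_summary`) with one row per
#'   (configuration, model); per-run detail in `attr(, "runs")`.
#' @export
run_study <- function(configs, models = c("direct", "two_stage", "joint"),
                      n_runs = NULL, seed = 1L,
                      inference = inference_config(seed = seed),
                      map_metrics = TRUE,
                      map_models = c("two_stage", "joint"),
                      progress = FALSE) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  models <- match.arg(models, several.ok = TRUE)
  rows <- list(); run_rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    nr <- n_runs %||% cfg$n_runs
    seeds <- child_seeds(seed, nr, salt = ci)
    use_models <- models
    if (cfg$misalignment && "direct" %in% use_models)
      use_models <- setdiff(use_models, "direct")
    acc <- list()
    n_failed <- stats::setNames(integer(length(use_models)), use_models)
    for (r in seq_len(nr)) {
      ds <- generate_dataset(cfg, seeds[r])
      res <- run_one(ds, use_models, inference, map_metrics, map_models)
      for (m in use_models) {
        if (is.null(res[[m]])) { n_failed[m] <- n_failed[m] + 1L; next }
        acc[[m]] <- rbind(acc[[m]],
                          cbind(data.frame(config = ci, run = r,
                                           seed = seeds[r], model = m),
                                res[[m]]))
      }
      if (progress)
        message(sprintf("config %d run %d/%d done", ci, r, nr))
    }
    for (m in use_models) {
      a <- acc[[m]]
      if (is.null(a)) next
      rows[[length(rows) + 1]] <- data.frame(
        misaligned = cfg$misalignment,
        measurement_error = cfg$measurement_error,
        model = m,
        mean_beta1 = mean(a$beta1_mean),
        mean_sd_beta1 = mean(a$beta1_sd),
        rmse_beta1 = sqrt(mean((a$beta1_mean - cfg$betas[2])^2)),
        rmse_species_map = mean(a$rmse_species_map),
        rmse_covariate_map = mean(a$rmse_covariate_map),
        n_runs = nrow(a), n_failed = n_failed[m])
      run_rows[[length(run_rows) + 1]] <- a
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "runs") <- do.call(rbind, run_rows)
  class(out) <- c("study_summary", class(out))
  out
}

# fit the applicable models to one data set and score them
run_one <- function(ds, use_models, inference, map_metrics, map_models) {
  spec <- simulation_sdm_spec()
  priors <- prior_config()
  out <- list()
  needs_stage1 <- any(c("two_stage", "joint") %in% use_models)
  stage1 <- NULL
  if (needs_stage1) {
    stage1 <- tryCatch(
      sdm_stage1(ds$species, ds$abiotic, spec, priors, inference),
      error = function(e) { warning("stage-1 failure: ", conditionMessage(e)); NULL })
  }
  ts_fit <- NULL
  for (m in use_models) {
    fit <- tryCatch({
      if (m == "direct") {
        sdm_engine_fit(ds$species, spec, inference,
                       known_cov = ds$species$covariates, kind = "direct")
      } else if (m == "two_stage") {
        if (is.null(stage1)) stop("no stage-1 fits")
        known <- as.data.frame(lapply(stage1, function(s)
          krig_collapse(s, ds$species$points, cov = FALSE)$mean))
        ts_fit <- sdm_engine_fit(ds$species, spec, inference,
                                 known_cov = known, stage1 = stage1,
                                 kind = "two_stage")
        ts_fit
      } else {
        if (is.null(stage1)) stop("no stage-1 fits")
        eiv <- lapply(stage1, function(s)
          krig_collapse(s, ds$species$points, cov = TRUE))
        # start the joint coefficient hyperparameters from this run's
        # two-stage estimates (same data, simpler model); the spatial
        # hyperparameters start from the generic defaults, which keeps the
        # optimizer in the well-behaved basin even when the two-stage
        # spatial mode is degenerate
        ti <- NULL
        if (!is.null(ts_fit)) {
          co <- ts_fit$coefficients
          diam <- sqrt(diff(range(ds$species$points$x))^2 +
                         diff(range(ds$species$points$y))^2)
          ti <- c(co$mean[match(names(eiv), co$term)],
                  log(0.5), log(max(diam / 3, 1e-3)))
        }
        sdm_engine_fit(ds$species, spec, inference, known_cov = NULL,
                       eiv = eiv, stage1 = stage1, kind = "joint",
                       theta_init = ti)
      }
    }, error = function(e) {
      warning(sprintf("%s fit failed: %s", m, conditionMessage(e))); NULL })
    if (is.null(fit)) { out[m] <- list(NULL); next }
    i1 <- match("x1", fit$coefficients$term)
    sc <- data.frame(beta1_mean = fit$coefficients$mean[i1],
                     beta1_sd = fit$coefficients$sd[i1],
                     rmse_species_map = NA_real_,
                     rmse_covariate_map = NA_real_)
    if (map_metrics && m != "direct" && m %in% map_models) {
      mp <- tryCatch(predict_occurrence_map(fit, ds$truth$grid),
                     error = function(e) {
                       warning("map prediction failed: ", conditionMessage(e))
                       NULL })
      if (!is.null(mp)) {
        sc$rmse_species_map <-
          sqrt(mean((mp$probability$mean - ds$truth$mu_grid)^2))
        sc$rmse_covariate_map <-
          sqrt(mean((mp$covariates$x1$mean - ds$truth$X1_grid)^2))
      }
    }
    out[[m]] <- sc
  }
  out
}

#' Closed-form attenuation of linear effects under classical error
#'
#' For the linear-Gaussian analogue of regression dilution: with true
#' covariates of covariance `Sigma` observed with independent N(0, delta2)
#' error, the large-sample linear-regression coefficients shrink to
#' (Sigma + delta2 I)^-1 Sigma beta. Used as an independent analytic bound
#' when interpreting the direct model's attenuation (the logistic link and
#' the spatial residual dilute further).
#'
#' @param Sigma covariance matrix of the true covariates (positive definite).
#' @param delta2 measurement-error variance >= 0.
#' @param beta true coefficient vector.
#' @return Attenuated coefficient vector.
#' @export
attenuation_oracle <- function(Sigma, delta2, beta) {
  Sigma <- as.matrix(Sigma)
  if (delta2 < 0) stop("delta2 must be >= 0")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  as.vector(solve(Sigma + diag(delta2, nrow(Sigma)), Sigma %*% beta))
}
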