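#' Prior configuration
#'
#' Default priors follow the vague-prior convention of latent Gaussian
#' modelling software: fixed effects (intercepts and regression coefficients)
#' get N(0, 1000); observation and spline precisions 1/delta^2 and 1/zeta^2
#' get Gamma(shape 1, rate 1e-5); and the log variance and log range of
#' Matern fields get N(0, sd = sqrt(10)), read on the variance scale.
#'
#' @param fixed_effect_variance prior variance of fixed effects (default 1000).
#' @param precision_shape,precision_rate Gamma prior on precisions.
#' @param log_hyper_sd prior sd of log variance / log range hyperparameters.
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(fixed_effect_variance = 1000,
                         precision_shape = 1, precision_rate = 1e-5,
                         log_hyper_sd = sqrt(10)) {
  stopifnot(fixed_effect_variance > 0, precision_shape > 0,
            precision_rate > 0, log_hyper_sd > 0)
  structure(list(fixed_effect_variance = fixed_effect_variance,
                 precision_shape = precision_shape,
                 precision_rate = precision_rate,
                 log_hyper_sd = log_hyper_sd),
            class = "prior_config")
}

#' Inference configuration
#'
#' Settings of the nested Laplace engine: the outer optimization over
#' log-scale hyperparameters, the deterministic hyperparameter exploration
#' used to propagate hyperparameter uncertainty, and the number of posterior
#' draws used for summaries that require sampling.
#'
#' @param seed master seed for every stochastic step downstream of the fit.
#' @param n_draws posterior draws for draw-based summaries (warn below 500).
#' @param map_draws joint draws used to summarize prediction maps.
#' @param optim_maxit,optim_reltol Nelder-Mead settings for the outer
#'   hyperparameter optimization.
#' @param hyper_step step (in posterior-sd units) of the hyperparameter
#'   exploration points around the mode.
#' @param max_seconds soft runtime budget per fit; exceeded budgets flag the
#'   fit rather than abort it.
#' @param feedback `"latent"` (default): species data update latent covariate
#'   values but covariate-field hyperparameters stay at their kriging
#'   posteriors; `"full"`: covariate hyperparameters join the outer
#'   optimization of the joint model.
#' @return Object of class `inference_config`.
#' @export
inference_config <- function(seed = 1L, n_draws = 1000L, map_draws = 150L,
                             optim_maxit = 250L, optim_reltol = 1e-5,
                             hyper_step = 1.1, max_seconds = Inf,
                             feedback = c("latent", "full")) {
  if (n_draws < 500)
    warning("fewer than 500 draws; reported draw-based summaries will be noisy")
  structure(list(seed = as.integer(seed), n_draws = as.integer(n_draws),
                 map_draws = as.integer(map_draws),
                 optim_maxit = optim_maxit, optim_reltol = optim_reltol,
                 hyper_step = hyper_step, max_seconds = max_seconds,
                 feedback = match.arg(feedback)),
            class = "inference_config")
}

# log prior of precision-scale Gamma(a, b) expressed on t = log(variance):
# tau = exp(-t), p(t) = Gamma(tau; a, b) * tau
lp_logvar_gamma_prec <- function(t, shape, rate) {
  stats::dgamma(exp(-t), shape = shape, rate = rate, log = TRUE) - t
}

# Gaussian log-marginal of a kriging model with the intercept integrated out:
# y ~ N(0, sigma2 R(range) + delta2 I + Valpha 11')
krig_logml <- function(y, D, th, Valpha, rcache = NULL) {
  s2 <- exp(th[1]); rg <- exp(th[2]); d2 <- exp(th[3])
  n <- length(y)
  R <- NULL
  if (!is.null(rcache)) {
    key <- sprintf("%.12g", rg)
    if (!is.na(match(key, rcache$keys))) R <- rcache[[key]]
  }
  if (is.null(R)) {
    R <- matrix(matern_correlation(as.vector(D), rg), n, n)
    if (!is.null(rcache)) {
      if (length(rcache$keys) >= 3) {
        rm(list = rcache$keys[1], envir = rcache)
        rcache$keys <- rcache$keys[-1]
      }
      rcache$keys <- c(rcache$keys, key); rcache[[key]] <- R
    }
  }
  K <- s2 * R + Valpha
  diag(K) <- diag(K) + d2 + matern_jitter * (s2 + d2)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-1e10)
  q <- sum(forwardsolve(t(L), y)^2)
  -sum(log(diag(L))) - 0.5 * q
}

#' Bayesian kriging of one noisy covariate field
#'
#' Fits the latent-field model X*(a) = alpha + G(a) + eps with
#' G ~ Matern(sigma^2, range), eps ~ N(0, delta^2) to point observations.
#' The intercept is integrated out analytically; the three log-scale
#' hyperparameters (log sigma^2, log range, log delta^2) are optimized under
#' the priors in `priors` and their uncertainty is propagated by a
#' deterministic set of exploration points around the posterior mode.
#'
#' @param obs a `field_realization` of observed values (>= 10 observations
#'   recommended; fewer triggers a warning).
#' @param priors a [prior_config()].
#' @param inference an [inference_config()].
#' @param targets optional point set at which latent-field summaries are
#'   computed immediately (can also be done later via [predict_field()]).
#' @return Object of class `krig_fit` with elements `hyper` (posterior
#'   summary table for alpha, sigma2, range, delta2), `latent` (data frame of
#'   mean/sd at `targets`, if given), `hx` (hyperparameter exploration),
#'   `diagnostics`, and a `draws(targets, n, seed)` accessor returning joint
#'   posterior samples of the latent field.
#' @export
fit_latent_field <- function(obs, priors = prior_config(),
                             inference = inference_config(), targets = NULL,
                             theta_init = NULL) {
  stopifnot(inherits(obs, "field_realization"))
  n <- nrow(obs$points)
  if (n < 10) warning("fewer than 10 observations; hyperparameters are weakly identified")
  y <- obs$values
  D <- cross_dist(obs$points, obs$points)
  Va <- priors$fixed_effect_variance
  sh <- priors$log_hyper_sd
  rcache <- new.env(parent = emptyenv()); rcache$keys <- character()
  logpost <- function(th) {
    krig_logml(y, D, th, Va, rcache) +
      stats::dnorm(th[1], 0, sh, log = TRUE) +
      stats::dnorm(th[2], 0, sh, log = TRUE) +
      lp_logvar_gamma_prec(th[3], priors$precision_shape, priors$precision_rate)
  }
  diam <- sqrt(diff(range(obs$points$x))^2 + diff(range(obs$points$y))^2)
  v0 <- max(stats::var(y), 1e-4)
  init <- theta_init %||% c(log(v0 / 2), log(max(diam / 3, 1e-3)), log(v0 / 2))
  hx <- hyper_explore(logpost, init, step = inference$hyper_step,
                      maxit = inference$optim_maxit,
                      reltol = inference$optim_reltol)
  hyper <- hyper_summary_table(hx, c("sigma2", "range", "delta2"))
  # intercept posterior per exploration point (closed form), then mixed
  ab <- vapply(hx$points, function(th) krig_alpha_post(y, D, th, Va),
               numeric(2))
  amix <- mix_moments(ab[1, , drop = FALSE], ab[2, , drop = FALSE], hx$weights)
  hyper <- rbind(data.frame(parameter = "alpha", mean = amix$mean,
                            sd = amix$sd,
                            q2.5 = amix$mean - 1.96 * amix$sd,
                            q97.5 = amix$mean + 1.96 * amix$sd),
                 hyper)
  fit <- structure(list(obs = obs, priors = priors, inference = inference,
                        hx = hx, Valpha = Va, hyper = hyper,
                        diagnostics = list(converged = hx$converged,
                                           logpost_mode = hx$logpost_mode)),
                   class = "krig_fit")
  fit$draws <- function(targets, n, seed = inference$seed) {
    krig_latent_draws(fit, targets, n, seed)
  }
  if (!is.null(targets)) {
    cm <- krig_collapse(fit, targets, cov = FALSE)
    fit$latent <- data.frame(x = as_points(targets)$x, y = as_points(targets)$y,
                             mean = cm$mean, sd = sqrt(cm$var))
  }
  fit
}

# closed-form intercept posterior (mean, sd) given hyperparameters
krig_alpha_post <- function(y, D, th, Valpha) {
  s2 <- exp(th[1]); rg <- exp(th[2]); d2 <- exp(th[3])
  n <- length(y)
  Q <- s2 * matrix(matern_correlation(as.vector(D), rg), n, n)
  diag(Q) <- diag(Q) + d2 + matern_jitter * (s2 + d2)
  L <- chol(Q)
  u1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  prec <- sum(u1) + 1 / Valpha
  c(sum(u1 * y) / prec, sqrt(1 / prec))
}

# conditional law of the latent field (incl. intercept) at targets for one
# hyperparameter point: covariance augmented with Valpha absorbs alpha.
krig_conditional_at <- function(obs, th, Valpha, targets, cov = TRUE) {
  s2 <- exp(th[1]); rg <- exp(th[2]); d2 <- exp(th[3])
  p <- matern_params(s2, rg)
  targets <- as_points(targets)
  Coo <- matern_covariance_matrix(obs$points, p) + Valpha
  diag(Coo) <- diag(Coo) + d2 + matern_jitter * (s2 + d2)
  Cto <- matern_cross_cov(targets, obs$points, p) + Valpha
  L <- chol(Coo)
  w <- backsolve(L, forwardsolve(t(L), obs$values))
  mean <- as.vector(Cto %*% w)
  half <- forwardsolve(t(L), t(Cto))
  if (cov) {
    Ctt <- matern_covariance_matrix(targets, p) + Valpha
    V <- Ctt - crossprod(half)
    d <- diag(V); d[d < 0] <- 0; diag(V) <- d
    list(mean = mean, cov = V)
  } else {
    vt <- s2 + Valpha - colSums(half^2)
    list(mean = mean, var = pmax(vt, 0))
  }
}

# collapse the hyperparameter mixture of conditional laws at targets into a
# single Gaussian (moment matching); cov = TRUE returns the full covariance.
krig_collapse <- function(fit, targets, cov = FALSE) {
  pts <- fit$hx$points; wt <- fit$hx$weights
  targets <- as_points(targets)
  nt <- nrow(targets)
  m <- numeric(nt)
  if (cov) Vt <- matrix(0, nt, nt) else vt <- numeric(nt)
  ms <- vector("list", length(pts))
  for (t in seq_along(pts)) {
    cc <- krig_conditional_at(fit$obs, pts[[t]], fit$Valpha, targets, cov = cov)
    ms[[t]] <- cc$mean
    m <- m + wt[t] * cc$mean
    if (cov) Vt <- Vt + wt[t] * (cc$cov + tcrossprod(cc$mean))
    else vt <- vt + wt[t] * (cc$var + cc$mean^2)
  }
  if (cov) {
    Vt <- Vt - tcrossprod(m)
    Vt <- (Vt + t(Vt)) / 2
    list(mean = m, cov = Vt)
  } else list(mean = m, var = pmax(vt - m^2, 0))
}

# joint posterior draws of the latent field at targets (hyperparameter point
# sampled by weight, then a MVN draw from the conditional law)
krig_latent_draws <- function(fit, targets, n, seed) {
  targets <- as_points(targets)
  with_seed(seed, {
    idx <- sample.int(length(fit$hx$points), n, replace = TRUE,
                      prob = fit$hx$weights)
    out <- matrix(0, nrow(targets), n)
    for (t in unique(idx)) {
      cc <- krig_conditional_at(fit$obs, fit$hx$points[[t]], fit$Valpha,
                                targets, cov = TRUE)
      L <- chol_cov(cc$cov, scale = max(mean(diag(cc$cov)), 1e-12))
      sel <- which(idx == t)
      z <- matrix(stats::rnorm(nrow(targets) * length(sel)), nrow(targets))
      out[, sel] <- cc$mean + crossprod(L, z)
    }
    out
  })
}

#' Posterior mean/sd map of a kriged latent field
#'
#' @param post a `krig_fit` from [fit_latent_field()].
#' @param grid a [prediction_grid()].
#' @return A [grid_map()] of the noise-free latent field (per-cell posterior
#'   mean and sd, mixed over the hyperparameter exploration points).
#' @export
predict_field <- function(post, grid) {
  stopifnot(inherits(post, "krig_fit"), inherits(grid, "prediction_grid"))
  ctr <- grid_centres(grid)
  if (nrow(ctr) == 0) stop("empty prediction grid")
  cm <- krig_collapse(post, ctr, cov = FALSE)
  mean <- cm$mean; sd <- sqrt(cm$var)
  if (!is.null(grid$mask)) { mean[!grid$mask] <- NA; sd[!grid$mask] <- NA }
  grid_map(grid, mean, sd, quantity = "covariate")
}
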