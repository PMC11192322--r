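#' Kriging model for one covariate field
#'
#' Describes the latent Gaussian field behind noisy point observations of one
#' covariate: a constant mean (intercept) alpha, a Matern (nu = 1) covariance
#' for the spatial signal, and an observation-level measurement-error
#' ("nugget") variance delta^2 added on top of the latent field.
#'
#' @param intercept field mean alpha.
#' @param matern [matern_params()] for the latent field.
#' @param noise_variance measurement-error variance delta^2 >= 0.
#' @return Object of class `latent_field_model`.
#' @export
latent_field_model <- function(intercept, matern, noise_variance) {
  stopifnot(inherits(matern, "matern_params"))
  if (!is.numeric(noise_variance) || noise_variance < 0)
    stop("noise_variance must be >= 0")
  structure(list(intercept = intercept, matern = matern,
                 noise_variance = noise_variance),
            class = "latent_field_model")
}

#' Exact Gaussian conditioning of a latent field on noisy observations
#'
#' Closed-form conditional law of the noise-free latent field at `targets`
#' given observations `obs` under the model
#' X*(a) = X(a) + eps, X ~ GP(alpha, Matern), eps ~ N(0, delta^2), with all
#' model parameters fixed and known. This is simple kriging: the returned mean
#' interpolates the data exactly when delta^2 = 0 and reverts to alpha (with
#' variance sigma^2) far from all observations.
#'
#' @param obs a `field_realization` of observed values.
#' @param model a [latent_field_model()].
#' @param targets point set at which the latent field is wanted.
#' @return List with `mean` (length = number of targets) and `cov`
#'   (conditional covariance matrix of the latent field at the targets).
#' @export
gp_conditional <- function(obs, model, targets) {
  stopifnot(inherits(obs, "field_realization"),
            inherits(model, "latent_field_model"))
  targets <- as_points(targets)
  p <- model$matern
  Coo <- matern_covariance_matrix(obs$points, p)
  Kd <- Coo + diag(model$noise_variance, nrow(Coo))
  Cto <- matern_cross_cov(targets, obs$points, p)
  Ctt <- matern_covariance_matrix(targets, p)
  L <- chol_cov(Kd, scale = p$variance + model$noise_variance)
  r <- obs$values - model$intercept
  w <- backsolve(L, forwardsolve(t(L), r))
  mean <- model$intercept + as.vector(Cto %*% w)
  half <- forwardsolve(t(L), t(Cto))      # (n_obs x n_targets)
  cov <- Ctt - crossprod(half)
  # numerical floor: conditional variances cannot be negative
  d <- diag(cov); d[d < 0] <- 0; diag(cov) <- d
  list(mean = mean, cov = cov)
}
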