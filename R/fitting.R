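# Fitting strategies for the species distribution model.
#
# Three estimators share one latent-Gaussian logistic engine (see laplace.R):
#   direct     — observed covariate values treated as exact (only possible for
#                spatially aligned data); attenuated under measurement error.
#   two_stage  — kriging posterior means plugged in as known constants.
#   joint      — latent covariate values at the species locations kept as
#                random variables (errors-in-variables); species data feed
#                back into the covariate posterior.
#
# Hyperparameters are optimized on the Laplace marginal posterior and their
# uncertainty is propagated by mixing over deterministic exploration points.
# For the joint model the coefficients of the uncertain covariates are part
# of the hyperparameter vector (conditional on them the latent problem is
# strictly log-concave), mirroring how measurement-error models are handled
# in latent-Gaussian software.

# ---- internal: design construction ----------------------------------------

# Build the fixed design and spline structures; covariates named in
# eiv_names are latent and do not enter the fixed design.
sdm_build <- function(species, spec, known_cov, eiv_names = character()) {
  n <- length(species$y)
  cols <- list(); colnames_ <- character(); Vb <- numeric()
  Vfix <- spec$priors$fixed_effect_variance
  if (spec$intercept) {
    cols[[length(cols) + 1]] <- rep(1, n)
    colnames_ <- c(colnames_, "(Intercept)"); Vb <- c(Vb, Vfix)
  }
  for (nm in setdiff(spec$linear, eiv_names)) {
    if (is.null(known_cov[[nm]]) || anyNA(known_cov[[nm]]))
      stop("covariate '", nm, "' is missing at species locations; ",
           "use the two_stage or joint model", call. = FALSE)
    cols[[length(cols) + 1]] <- known_cov[[nm]]
    colnames_ <- c(colnames_, nm); Vb <- c(Vb, Vfix)
  }
  splines <- list()
  for (nm in spec$splines) {
    zv <- known_cov[[nm]]
    if (is.null(zv) || anyNA(zv))
      stop("spline covariate '", nm, "' is missing at species locations",
           call. = FALSE)
    bn <- bin_covariate(zv, spec$spline_bins)
    bas <- rw2_basis(spec$spline_bins)
    cols[[length(cols) + 1]] <- bas$T[bn$assignment]
    colnames_ <- c(colnames_, paste0("f(", nm, "):trend")); Vb <- c(Vb, Vfix)
    splines[[nm]] <- list(bin = bn, basis = bas,
                          B = bas$L[bn$assignment, , drop = FALSE],
                          trend_col = length(cols))
  }
  Xf <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  colnames(Xf) <- colnames_
  list(Xf = Xf, Vb = Vb, splines = splines, eiv_names = eiv_names)
}

# hyperparameter layout: eiv coefficients first, then (log sigma0^2,
# log range0) if spatial, then one log zeta^2 per spline
sdm_theta_layout <- function(spec, eiv_names = character()) {
  nm <- character(0)
  if (length(eiv_names)) nm <- paste0("beta_", eiv_names)
  if (spec$spatial) nm <- c(nm, "log_sigma0sq", "log_range0")
  if (length(spec$splines)) nm <- c(nm, paste0("log_zeta2_", spec$splines))
  nm
}

# ---- internal: shared engine ----------------------------------------------

sdm_engine_fit <- function(species, spec, inference, known_cov = NULL,
                           eiv = list(), stage1 = NULL, kind,
                           theta_init = NULL, extra_logpost = NULL) {
  t_start <- proc.time()[3]
  y <- species$y; n <- length(y)
  eiv_names <- names(eiv)
  bld <- sdm_build(species, spec, known_cov, eiv_names)
  th_names <- sdm_theta_layout(spec, eiv_names)
  n_eiv <- length(eiv_names)
  sp_off <- n_eiv                         # offset of the spatial block
  zt_off <- n_eiv + if (spec$spatial) 2L else 0L
  pri <- spec$priors
  if (spec$spatial) {
    dl <- as.vector(stats::dist(cbind(species$points$x, species$points$y)))
    lt <- lower.tri(matrix(0, n, n))
    # correlation matrices keyed by range: axis moves of the finite-difference
    # Hessian repeat ranges, so a tiny cache removes most Bessel evaluations
    rcache <- new.env(parent = emptyenv()); rcache$keys <- character()
    get_R <- function(r0) {
      key <- sprintf("%.12g", r0)
      hit <- match(key, rcache$keys)
      if (!is.na(hit)) return(rcache[[key]])
      R <- matrix(0, n, n)
      R[lt] <- matern_correlation(dl, r0)
      R <- R + t(R); diag(R) <- 1
      if (length(rcache$keys) >= 3) {
        rm(list = rcache$keys[1], envir = rcache)
        rcache$keys <- rcache$keys[-1]
      }
      rcache$keys <- c(rcache$keys, key); rcache[[key]] <- R
      R
    }
  }
  build_smooth <- function(th) {
    sm <- list()
    if (spec$spatial) {
      s0 <- exp(th[sp_off + 1]); r0 <- exp(th[sp_off + 2])
      sm[[length(sm) + 1]] <- list(B = NULL, C = s0 * get_R(r0))
    }
    for (i in seq_along(spec$splines)) {
      nm <- spec$splines[i]
      sm[[length(sm) + 1]] <-
        list(B = bld$splines[[nm]]$B,
             C = diag(exp(th[zt_off + i]), ncol(bld$splines[[nm]]$B)))
    }
    sm
  }
  build_eiv <- function(th) {
    lapply(seq_len(n_eiv), function(j)
      list(b = th[j], m = eiv[[j]]$mean, C = eiv[[j]]$cov))
  }
  theta_prior <- function(th) {
    lp <- 0
    for (j in seq_len(n_eiv))
      lp <- lp + stats::dnorm(th[j], 0, sqrt(pri$fixed_effect_variance),
                              log = TRUE)
    if (spec$spatial)
      lp <- lp + stats::dnorm(th[sp_off + 1], 0, pri$log_hyper_sd, log = TRUE) +
        stats::dnorm(th[sp_off + 2], 0, pri$log_hyper_sd, log = TRUE)
    for (i in seq_along(spec$splines))
      lp <- lp + lp_logvar_gamma_prec(th[zt_off + i], pri$precision_shape,
                                      pri$precision_rate)
    lp
  }
  warm <- new.env(parent = emptyenv())
  warm$dual <- NULL; warm$keys <- character(); warm$fits <- list()
  laplace_at <- function(th) {
    key <- paste(format(th, digits = 17), collapse = ",")
    hit <- match(key, warm$keys)
    if (!is.na(hit)) return(warm$fits[[hit]])
    f <- lgm_laplace(y, bld$Xf, bld$Vb, smooth = build_smooth(th),
                     eiv = build_eiv(th), control = list(maxit = 60),
                     start = warm$dual)
    warm$dual <- f$dual
    # memoize a handful of recent fits: the exploration points are evaluated
    # for their weights first and refit for their summaries right after
    if (length(warm$keys) >= 12) {
      warm$keys <- warm$keys[-1]; warm$fits <- warm$fits[-1]
    }
    warm$keys <- c(warm$keys, key)
    warm$fits <- c(warm$fits, list(f))
    f
  }
  if (length(th_names) == 0) {
    f <- laplace_at(numeric(0))
    hx <- list(mode = numeric(0), points = list(numeric(0)), weights = 1,
               cov = matrix(0, 0, 0), converged = f$converged,
               logpost_mode = f$logml)
    fits <- list(f)
  } else {
    logpost <- function(th) {
      f <- laplace_at(th)
      lp <- f$logml + theta_prior(th)
      # Saturation barrier: when the latent mode drives the linear predictor
      # far beyond what binary observations can distinguish (|eta| of 20 is
      # p = 1 - 2e-9), the IRLS weights collapse and the Gauss-Newton
      # determinant no longer penalizes model complexity, so the Laplace
      # marginal likelihood is grossly overestimated -- a known failure of
      # Laplace approximations for Gaussian-process classification at
      # extreme variance hyperparameters. A smooth quadratic barrier
      # confines the hyperparameter search to the trustworthy region; it is
      # exactly zero wherever the fit is data-supported.
      sat <- max(abs(f$eta)) - 20
      if (sat > 0) lp <- lp - 50 * sat^2
      if (!is.null(extra_logpost)) lp <- lp + extra_logpost(th)
      lp
    }
    init <- theta_init %||% {
      i0 <- numeric(length(th_names))
      if (spec$spatial) {
        diam <- sqrt(diff(range(species$points$x))^2 +
                       diff(range(species$points$y))^2)
        i0[sp_off + 1:2] <- c(log(0.5), log(max(diam / 3, 1e-3)))
      }
      i0
    }
    # cross-curvature is computed within parameter blocks (eiv coefficients;
    # spatial variance/range); between-block couplings are near zero and
    # skipping them saves a third of the Hessian evaluations
    pairs <- list()
    if (n_eiv > 1)
      for (i in 1:(n_eiv - 1)) for (j in (i + 1):n_eiv)
        pairs[[length(pairs) + 1]] <- c(i, j)
    if (spec$spatial) pairs[[length(pairs) + 1]] <- sp_off + c(1, 2)
    hx <- hyper_explore(logpost, init, step = inference$hyper_step,
                        maxit = inference$optim_maxit,
                        reltol = inference$optim_reltol,
                        fd_pairs = pairs)
    fits <- lapply(hx$points, laplace_at)
  }
  wt <- hx$weights
  # conditional (Gaussian) fixed effects: mixture over exploration points
  p <- ncol(bld$Xf)
  bmeans <- matrix(vapply(fits, function(f) f$beta, numeric(p)), nrow = p)
  bvars <- matrix(vapply(fits, function(f) pmax(diag(f$beta_cov), 0),
                         numeric(p)), nrow = p)
  bm <- mix_moments(bmeans, bvars, wt)
  cond_tab <- data.frame(term = colnames(bld$Xf), mean = bm$mean, sd = bm$sd)
  # eiv coefficients live in the hyperparameter layer
  eiv_tab <- NULL
  if (n_eiv > 0) {
    em <- t(vapply(seq_len(n_eiv), function(j) hyper_coord_moments(hx, j),
                   numeric(2)))
    eiv_tab <- data.frame(term = eiv_names, mean = em[, 1], sd = em[, 2])
  }
  # assemble in display order: intercept, linear terms in spec order, trends
  tab <- rbind(cond_tab, eiv_tab)
  ord <- c("(Intercept)"[spec$intercept], spec$linear,
           if (length(spec$splines)) paste0("f(", spec$splines, "):trend"))
  tab <- tab[match(ord, tab$term), ]
  coefficients <- data.frame(term = tab$term, mean = tab$mean, sd = tab$sd,
                             q2.5 = tab$mean - 1.96 * tab$sd,
                             q97.5 = tab$mean + 1.96 * tab$sd)
  spatial_hyper <- NULL; spline_hyper <- NULL
  if (spec$spatial) {
    spatial_hyper <- hyper_summary_table(hx, c("sigma0sq", "range0"),
                                         idx = sp_off + 1:2)
  }
  if (length(spec$splines)) {
    spline_hyper <- hyper_summary_table(hx, paste0("zeta2_", spec$splines),
                                        idx = zt_off + seq_along(spec$splines))
  }
  elapsed <- proc.time()[3] - t_start
  if (is.finite(inference$max_seconds) && elapsed > inference$max_seconds)
    warning(sprintf("fit exceeded its %gs budget (%.1fs)",
                    inference$max_seconds, elapsed))
  converged <- (is.null(hx$converged) || isTRUE(hx$converged)) &&
    all(vapply(fits, function(f) f$converged, logical(1)))
  if (!converged)
    warning("fit flagged as not converged; inspect $diagnostics")
  fit <- structure(list(
    kind = kind, spec = spec, species = species,
    coefficients = coefficients,
    spatial_hyper = spatial_hyper, spline_hyper = spline_hyper,
    stage1 = stage1, hx = hx, fits = fits, build = bld,
    eiv = eiv, inference = inference,
    diagnostics = list(converged = converged, elapsed_seconds = elapsed,
                       hyper_mode = stats::setNames(hx$mode, th_names),
                       laplace_iterations =
                         vapply(fits, function(f) f$iterations, numeric(1))),
    splines = NULL), class = "sdm_fit")
  fit$draws <- function(n, seed = inference$seed) sdm_fit_draws(fit, n, seed)
  if (exists("logpost", inherits = FALSE)) fit$logpost <- logpost
  if (length(spec$splines))
    fit$splines <- sdm_spline_tables(fit, n_draws = max(500, inference$n_draws))
  fit
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("sdm_fit (%s model), %d observations\n", x$kind,
              length(x$species$y)))
  print(x$coefficients, row.names = FALSE)
  if (!is.null(x$spatial_hyper)) {
    cat("spatial residual:\n"); print(x$spatial_hyper, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.sdm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$mean, object$coefficients$term)
}

# joint posterior draws of every latent component; beta is returned in
# coefficient-table order (eiv coefficients take the value of the sampled
# hyperparameter point).
sdm_fit_draws <- function(fit, n, seed) {
  with_seed(seed, {
    wt <- fit$hx$weights
    idx <- if (length(wt) == 1) rep(1L, n)
      else sample.int(length(wt), n, replace = TRUE, prob = wt)
    nobs <- length(fit$species$y)
    terms <- fit$coefficients$term
    beta <- matrix(0, length(terms), n, dimnames = list(terms, NULL))
    nsm <- length(fit$fits[[1]]$mod$smooth)
    u <- lapply(seq_len(nsm), function(k)
      matrix(0, ncol(fit$fits[[1]]$mod$smooth[[k]]$C), n))
    v <- lapply(fit$eiv, function(e) matrix(0, nobs, n))
    eta <- matrix(0, nobs, n)
    eiv_chols <- lapply(fit$eiv, function(e) chol_cov(e$cov))
    cond_terms <- colnames(fit$build$Xf)
    for (t in unique(idx)) {
      sel <- which(idx == t)
      f <- fit$fits[[t]]
      cc <- list(smooth = lapply(f$mod$smooth, function(s) chol_cov(s$C)),
                 eiv = eiv_chols)
      d <- lgm_draws(f, length(sel), chol_cache = cc)
      beta[cond_terms, sel] <- d$beta
      for (j in seq_along(fit$eiv))
        beta[names(fit$eiv)[j], sel] <- fit$hx$points[[t]][j]
      for (k in seq_len(nsm)) u[[k]][, sel] <- d$u[[k]]
      for (j in seq_along(v)) v[[j]][, sel] <- d$v[[j]]
      e <- fit$build$Xf %*% d$beta
      for (k in seq_len(nsm)) {
        B <- f$mod$smooth[[k]]$B
        e <- e + if (is.null(B)) d$u[[k]] else B %*% d$u[[k]]
      }
      for (j in seq_along(fit$eiv))
        e <- e + fit$hx$points[[t]][j] * d$v[[j]]
      eta[, sel] <- e
    }
    list(beta = beta, eta = eta, mu = stats::plogis(eta), u = u, v = v,
         point = idx)
  })
}

# posterior mean/sd per bin for each fitted spline, by sampling
sdm_spline_tables <- function(fit, n_draws = 500) {
  d <- sdm_fit_draws(fit, n_draws, fit$inference$seed + 101L)
  out <- list()
  smi <- if (fit$spec$spatial) 1L else 0L
  for (i in seq_along(fit$spec$splines)) {
    nm <- fit$spec$splines[i]
    sp <- fit$build$splines[[nm]]
    g <- d$beta[paste0("f(", nm, "):trend"), ]
    fbin <- outer(sp$basis$T, g) + sp$basis$L %*% d$u[[smi + i]]
    out[[nm]] <- data.frame(
      bin_midpoint = sp$bin$midpoints,
      mean = rowMeans(fbin), sd = apply(fbin, 1, stats::sd),
      q2.5 = apply(fbin, 1, stats::quantile, 0.025),
      q97.5 = apply(fbin, 1, stats::quantile, 0.975))
  }
  out
}

# ---- the three estimators --------------------------------------------------

#' Fit the Direct model (observed covariates treated as exact)
#'
#' Bayesian logistic GAMM that uses the observed (possibly noisy) covariate
#' values at the species locations as if they were the truth. Only possible
#' for spatially aligned data; under classical measurement error its linear
#' effects are attenuated (regression dilution).
#'
#' @param obs a [species_observations()] whose `covariates` table holds every
#'   covariate named in the spec at every location.
#' @param spec an [sdm_spec()].
#' @param inference an [inference_config()].
#' @return An `sdm_fit` of kind `"direct"`.
#' @export
fit_direct <- function(obs, spec, inference = inference_config()) {
  stopifnot(inherits(obs, "species_observations"), inherits(spec, "sdm_spec"))
  sdm_engine_fit(obs, spec, inference, known_cov = obs$covariates,
                 kind = "direct")
}

# stage 1 for two_stage/joint: one kriging fit per uncertain covariate
sdm_stage1 <- function(species, abiotic, spec, priors, inference,
                       theta_init = NULL) {
  if (!all(names(abiotic) %in% spec$linear))
    stop("every abiotic covariate must appear among the spec's linear terms")
  out <- lapply(names(abiotic), function(nm)
    fit_latent_field(abiotic[[nm]], priors, inference,
                     theta_init = theta_init[[nm]]))
  names(out) <- names(abiotic)
  out
}

#' Fit the Two-Stage model (kriging means plugged in)
#'
#' Stage 1 fits an independent kriging model per uncertain covariate; stage 2
#' fits the logistic GAMM treating the kriging posterior means at the species
#' locations as known constants. Fast, but ignores covariate uncertainty.
#'
#' @param species a [species_observations()].
#' @param abiotic named list of `field_realization` objects, one per uncertain
#'   covariate (names must match linear terms of the spec). Covariates of the
#'   spec not in this list must be present in `species$covariates`.
#' @param spec an [sdm_spec()].
#' @param priors a [prior_config()] for the kriging models.
#' @param inference an [inference_config()].
#' @param stage1 optional precomputed list of `krig_fit` objects (one per
#'   abiotic covariate), e.g. to share stage 1 with [fit_joint()].
#' @return An `sdm_fit` of kind `"two_stage"` with `$stage1` holding the
#'   kriging fits.
#' @export
fit_two_stage <- function(species, abiotic, spec, priors = prior_config(),
                          inference = inference_config(), stage1 = NULL) {
  stopifnot(inherits(species, "species_observations"))
  if (length(abiotic) == 0)
    return(fit_direct(species, spec, inference))
  stage1 <- stage1 %||% sdm_stage1(species, abiotic, spec, priors, inference)
  known <- as.data.frame(species$covariates %||%
                           matrix(nrow = length(species$y), ncol = 0))
  for (nm in names(stage1))
    known[[nm]] <- krig_collapse(stage1[[nm]], species$points, cov = FALSE)$mean
  fit <- sdm_engine_fit(species, spec, inference, known_cov = known,
                        stage1 = stage1, kind = "two_stage")
  if (any(!vapply(stage1, function(s) s$diagnostics$converged, logical(1))))
    warning("one or more stage-1 kriging fits flagged as not converged")
  fit
}

#' Fit the Joint errors-in-variables model
#'
#' The latent covariate values at the species locations are kept as random
#' variables: their kriging conditional law (given the abiotic observations)
#' is the prior, and the species likelihood updates them, so covariate
#' uncertainty propagates into the effect estimates and, conversely, species
#' data inform the covariate fields. The coefficients of the uncertain
#' covariates are estimated in the hyperparameter layer, conditional on which
#' the latent field problem is log-concave.
#'
#' With `inference$feedback = "latent"` (default) the covariate-field
#' hyperparameters stay at their stage-1 kriging posteriors and only the
#' latent values receive feedback; `"full"` folds the covariate
#' hyperparameters into the joint optimization.
#'
#' @inheritParams fit_two_stage
#' @return An `sdm_fit` of kind `"joint"`.
#' @export
fit_joint <- function(species, abiotic, spec, priors = prior_config(),
                      inference = inference_config(), stage1 = NULL) {
  stopifnot(inherits(species, "species_observations"))
  if (length(abiotic) == 0)
    return(fit_direct(species, spec, inference))
  stage1 <- stage1 %||% sdm_stage1(species, abiotic, spec, priors, inference)
  known <- as.data.frame(species$covariates %||%
                           matrix(nrow = length(species$y), ncol = 0))
  if (inference$feedback == "full")
    return(fit_joint_full(species, abiotic, spec, priors, inference, stage1,
                          known))
  eiv <- lapply(stage1, function(s) krig_collapse(s, species$points, cov = TRUE))
  sdm_engine_fit(species, spec, inference, known_cov = known,
                 eiv = eiv, stage1 = stage1, kind = "joint")
}

# full-feedback variant: the covariate-field hyperparameters join the outer
# optimization, with the kriging Gaussian marginal of the abiotic
# observations added to the objective so the species data can move them.
# The eiv conditional laws are rebuilt at the joint mode for the final fit.
fit_joint_full <- function(species, abiotic, spec, priors, inference, stage1,
                           known) {
  eiv_names <- names(abiotic)
  k_sdm <- length(sdm_theta_layout(spec, eiv_names))
  Ds <- lapply(abiotic, function(f) cross_dist(f$points, f$points))
  Va <- priors$fixed_effect_variance
  krig_idx <- function(j) k_sdm + 3 * (j - 1) + 1:3
  eiv_at <- function(th) {
    out <- list()
    for (j in seq_along(eiv_names)) {
      cc <- krig_conditional_at(abiotic[[j]], th[krig_idx(j)], Va,
                                species$points, cov = TRUE)
      out[[eiv_names[j]]] <- list(mean = cc$mean, cov = cc$cov)
    }
    out
  }
  # outer objective: SDM Laplace marginal at the implied eiv law plus the
  # kriging marginals and hyperpriors of the covariate fields
  krig_part <- function(th) {
    lp <- 0
    for (j in seq_along(eiv_names)) {
      thj <- th[krig_idx(j)]
      lp <- lp + krig_logml(abiotic[[j]]$values, Ds[[j]], thj, Va) +
        stats::dnorm(thj[1], 0, priors$log_hyper_sd, log = TRUE) +
        stats::dnorm(thj[2], 0, priors$log_hyper_sd, log = TRUE) +
        lp_logvar_gamma_prec(thj[3], priors$precision_shape,
                             priors$precision_rate)
    }
    lp
  }
  init <- c(rep(0, k_sdm), unlist(lapply(stage1, function(s) s$hx$mode)))
  if (spec$spatial) init[length(eiv_names) + 1:2] <- c(log(0.5), log(0.3))
  # one self-contained exploration over the concatenated vector; the inner
  # Laplace fit is rebuilt per evaluation with the th-implied eiv law
  n <- length(species$y)
  bld <- sdm_build(species, spec, known, eiv_names)
  dl <- if (spec$spatial)
    as.vector(stats::dist(cbind(species$points$x, species$points$y))) else NULL
  lt <- if (spec$spatial) lower.tri(matrix(0, n, n)) else NULL
  warm <- new.env(parent = emptyenv()); warm$dual <- NULL
  pri <- spec$priors
  sp_off <- length(eiv_names)
  logpost <- function(th) {
    e <- eiv_at(th)
    sm <- list()
    if (spec$spatial) {
      s0 <- exp(th[sp_off + 1]); r0 <- exp(th[sp_off + 2])
      C <- matrix(0, n, n); C[lt] <- s0 * matern_correlation(dl, r0)
      C <- C + t(C); diag(C) <- s0
      sm[[1]] <- list(B = NULL, C = C)
    }
    ec <- lapply(seq_along(e), function(j)
      list(b = th[j], m = e[[j]]$mean, C = e[[j]]$cov))
    f <- lgm_laplace(species$y, bld$Xf, bld$Vb, smooth = sm, eiv = ec,
                     control = list(maxit = 60), start = warm$dual)
    warm$dual <- f$dual
    lp <- f$logml + krig_part(th)
    for (j in seq_along(eiv_names))
      lp <- lp + stats::dnorm(th[j], 0, sqrt(pri$fixed_effect_variance),
                              log = TRUE)
    if (spec$spatial)
      lp <- lp + stats::dnorm(th[sp_off + 1], 0, pri$log_hyper_sd, log = TRUE) +
        stats::dnorm(th[sp_off + 2], 0, pri$log_hyper_sd, log = TRUE)
    lp
  }
  hx <- hyper_explore(logpost, init, step = inference$hyper_step,
                      maxit = max(inference$optim_maxit, 80 * length(init)),
                      reltol = inference$optim_reltol)
  e <- eiv_at(hx$mode)
  fit <- sdm_engine_fit(species, spec, inference, known_cov = known,
                        eiv = e, stage1 = stage1, kind = "joint",
                        theta_init = hx$mode[seq_len(k_sdm)])
  fit$diagnostics$full_feedback_mode <- hx$mode
  fit$diagnostics$full_feedback <- TRUE
  fit
}

# ---- prediction ------------------------------------------------------------

# Draws of eta at arbitrary new points for a fitted model. For two_stage the
# uncertain covariates enter as plug-in kriging means at the new points; for
# joint they are drawn from their conditional law given the latent values at
# the species locations (consistent with the collapse used in fitting).
# new_known_cov supplies covariates treated as exact (direct models, spline
# covariates); missing values mask the point.
sdm_predict_eta_draws <- function(fit, newpoints, new_known_cov = NULL,
                                  n_draws = NULL, seed = NULL,
                                  keep_cov_draws = FALSE) {
  newpoints <- as_points(newpoints)
  n_draws <- n_draws %||% fit$inference$map_draws
  seed <- seed %||% (fit$inference$seed + 7L)
  npts <- nrow(newpoints)
  spec <- fit$spec
  masked <- rep(FALSE, npts)
  cov_mean <- list(); cov_cond <- list()
  for (nm in spec$linear) {
    if (!is.null(fit$stage1) && nm %in% names(fit$stage1)) {
      if (fit$kind == "two_stage") {
        cov_mean[[nm]] <- krig_collapse(fit$stage1[[nm]], newpoints,
                                        cov = FALSE)$mean
      } else {
        cov_cond[[nm]] <- krig_union_conditional(fit$stage1[[nm]],
                                                 fit$species$points, newpoints,
                                                 fit$eiv[[nm]])
      }
    } else {
      v <- new_known_cov[[nm]]
      if (is.null(v)) stop("covariate '", nm, "' has no values at the ",
                           "prediction points", call. = FALSE)
      masked <- masked | is.na(v)
      cov_mean[[nm]] <- v
    }
  }
  spline_assign <- list()
  for (nm in spec$splines) {
    v <- new_known_cov[[nm]]
    if (is.null(v)) stop("spline covariate '", nm, "' has no values at the ",
                         "prediction points", call. = FALSE)
    masked <- masked | is.na(v)
    sp <- fit$build$splines[[nm]]
    spline_assign[[nm]] <- findInterval(v, sp$bin$edges,
                                        rightmost.closed = TRUE,
                                        all.inside = TRUE)
  }
  d <- sdm_fit_draws(fit, n_draws, seed)
  eta <- matrix(0, npts, n_draws)
  cov_draws <- list()
  bi <- match("(Intercept)", fit$coefficients$term)
  if (!is.na(bi))
    eta <- eta + matrix(d$beta["(Intercept)", ], npts, n_draws, byrow = TRUE)
  for (nm in spec$linear) {
    bdr <- d$beta[nm, ]
    if (!is.null(cov_mean[[nm]])) {
      eta <- eta + outer(ifelse(is.na(cov_mean[[nm]]), 0, cov_mean[[nm]]), bdr)
    } else {
      cc <- cov_cond[[nm]]
      vsp <- d$v[[match(nm, names(fit$eiv))]]
      xc <- cc$mean_g + cc$Bmat %*% (vsp - cc$mean_s)
      xg <- xc + sqrt(cc$var_g) * matrix(stats::rnorm(npts * n_draws), npts)
      if (keep_cov_draws)
        cov_draws[[nm]] <- list(cond_mean_draws = xc, var_g = cc$var_g)
      eta <- eta + xg * matrix(bdr, npts, n_draws, byrow = TRUE)
    }
  }
  smi <- 0L
  if (spec$spatial) {
    smi <- 1L
    eta <- eta + sdm_W_at(fit, newpoints, d)
  }
  for (i in seq_along(spec$splines)) {
    nm <- spec$splines[i]
    sp <- fit$build$splines[[nm]]
    g <- d$beta[paste0("f(", nm, "):trend"), ]
    fbin <- outer(sp$basis$T, g) + sp$basis$L %*% d$u[[smi + i]]
    eta <- eta + fbin[spline_assign[[nm]], , drop = FALSE]
  }
  eta[masked, ] <- NA
  list(eta = eta, masked = masked, cov_draws = cov_draws)
}

# conditional structure of a kriged field at new points given its latent
# values at the species locations: collapse the hyperparameter mixture over
# the union of (species, new) points, then condition the new-point block on
# the species block.
krig_union_conditional <- function(kfit, s_points, g_points, eiv) {
  s_points <- as_points(s_points); g_points <- as_points(g_points)
  ns <- nrow(s_points); ng <- nrow(g_points)
  wt <- kfit$hx$weights; pts <- kfit$hx$points
  m_s <- numeric(ns); m_g <- numeric(ng)
  d_g <- numeric(ng)
  acc_gs <- matrix(0, ng, ns)
  for (t in seq_along(pts)) {
    th <- pts[[t]]; s2 <- exp(th[1]); rg <- exp(th[2]); dd2 <- exp(th[3])
    p <- matern_params(s2, rg); Va <- kfit$Valpha
    obs <- kfit$obs
    Coo <- matern_covariance_matrix(obs$points, p) + Va
    diag(Coo) <- diag(Coo) + dd2 + matern_jitter * (s2 + dd2)
    L <- chol(Coo)
    w <- backsolve(L, forwardsolve(t(L), obs$values))
    Cso <- matern_cross_cov(s_points, obs$points, p) + Va
    Cgo <- matern_cross_cov(g_points, obs$points, p) + Va
    mean_s <- as.vector(Cso %*% w); mean_g <- as.vector(Cgo %*% w)
    half_s <- forwardsolve(t(L), t(Cso)); half_g <- forwardsolve(t(L), t(Cgo))
    Cgs <- matern_cross_cov(g_points, s_points, p) + Va -
      crossprod(half_g, half_s)
    var_g <- pmax(s2 + Va - colSums(half_g^2), 0)
    m_s <- m_s + wt[t] * mean_s
    m_g <- m_g + wt[t] * mean_g
    acc_gs <- acc_gs + wt[t] * (Cgs + tcrossprod(mean_g, mean_s))
    d_g <- d_g + wt[t] * (var_g + mean_g^2)
  }
  C_gs <- acc_gs - tcrossprod(m_g, m_s)
  var_g_tot <- pmax(d_g - m_g^2, 0)
  Lss <- chol_cov(eiv$cov, scale = max(mean(diag(eiv$cov)), 1e-12))
  Bmat <- t(backsolve(Lss, forwardsolve(t(Lss), t(C_gs))))
  var_cond <- pmax(var_g_tot - rowSums(Bmat * C_gs), 0)
  list(mean_s = eiv$mean, mean_g = m_g, Bmat = Bmat, var_g = var_cond)
}

# draws of the spatial residual W at new points given draws at the species
# locations, per hyperparameter point used for each draw
sdm_W_at <- function(fit, newpoints, d) {
  npts <- nrow(newpoints); n_draws <- ncol(d$eta)
  out <- matrix(0, npts, n_draws)
  sp_off <- length(fit$eiv)
  for (t in unique(d$point)) {
    sel <- which(d$point == t)
    th <- fit$hx$points[[t]]
    s0 <- exp(th[sp_off + 1]); r0 <- exp(th[sp_off + 2])
    p <- matern_params(s0, r0)
    Css <- matern_covariance_matrix(fit$species$points, p)
    L <- chol_cov(Css, scale = s0)
    Crs <- matern_cross_cov(newpoints, fit$species$points, p)
    half <- forwardsolve(t(L), t(Crs))
    vc <- pmax(s0 - colSums(half^2), 0)
    Ws <- d$u[[1]][, sel, drop = FALSE]
    sol <- backsolve(L, forwardsolve(t(L), Ws))
    out[, sel] <- Crs %*% sol +
      sqrt(vc) * matrix(stats::rnorm(npts * length(sel)), npts)
  }
  out
}

#' Predicted occurrence maps (log-odds and probability scale)
#'
#' Per-cell posterior mean and sd of the linear predictor eta and of the
#' occurrence probability mu over joint posterior draws; the probability
#' summaries average logistic(eta) draw-wise rather than transforming the
#' mean. For two-stage and joint fits, covariate maps of each kriged
#' covariate are returned as well (the joint covariate map includes the
#' feedback from the species data).
#'
#' @param fit an `sdm_fit`.
#' @param grid a [prediction_grid()].
#' @param grid_covariates optional data frame of exact covariate values per
#'   cell (needed for direct models with covariates and for spline terms);
#'   cells with missing values are masked and counted.
#' @param n_draws,seed posterior draws used (defaults from the fit's
#'   inference config).
#' @return List with `log_odds` and `probability` [grid_map()]s, a named list
#'   `covariates` of kriged-covariate maps, and `n_masked`.
#' @export
predict_occurrence_map <- function(fit, grid, grid_covariates = NULL,
                                   n_draws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "sdm_fit"), inherits(grid, "prediction_grid"))
  ctr <- grid_centres(grid)
  if (nrow(ctr) == 0) stop("empty prediction grid")
  if (fit$kind == "direct" &&
      length(setdiff(c(fit$spec$linear, fit$spec$splines),
                     names(grid_covariates))) > 0)
    stop("the direct model has no interpolation of covariates to the grid; ",
         "supply grid_covariates or use the two_stage/joint model")
  pr <- sdm_predict_eta_draws(fit, ctr, new_known_cov = grid_covariates,
                              n_draws = n_draws, seed = seed,
                              keep_cov_draws = TRUE)
  eta <- pr$eta
  if (!is.null(grid$mask)) eta[!grid$mask, ] <- NA
  mu <- stats::plogis(eta)
  mk_map <- function(m, q) grid_map(grid, rowMeans(m), apply(m, 1, stats::sd),
                                    quantity = q)
  covmaps <- list()
  for (nm in names(fit$stage1 %||% list())) {
    if (fit$kind == "two_stage") {
      covmaps[[nm]] <- predict_field(fit$stage1[[nm]], grid)
      covmaps[[nm]]$quantity <- nm
    } else {
      cd <- pr$cov_draws[[nm]]
      mean_g <- rowMeans(cd$cond_mean_draws)
      sd_g <- sqrt(pmax(apply(cd$cond_mean_draws, 1, stats::var) + cd$var_g, 0))
      covmaps[[nm]] <- grid_map(grid, mean_g, sd_g, quantity = nm)
    }
  }
  list(log_odds = mk_map(eta, "log_odds"),
       probability = mk_map(mu, "probability"),
       covariates = covmaps,
       n_masked = sum(pr$masked | !(grid$mask %||% TRUE)))
}

#' Compare two fitted models and their prediction maps
#'
#' Pearson correlation of coefficient posterior means, per-map Pearson
#' correlations over unmasked cells, and a side-by-side coefficient table.
#' Degenerate (constant) maps yield a correlation reported as `NA` with an
#' explanatory note rather than an error.
#'
#' @param fitA,fitB `sdm_fit` objects with the same spec.
#' @param mapsA,mapsB optional outputs of [predict_occurrence_map()] on the
#'   same grid.
#' @return List with `coefficient_correlation`, `coefficients` (side-by-side
#'   table), `map_correlations` (named vector, possibly with NA), `notes`.
#' @export
compare_models <- function(fitA, fitB, mapsA = NULL, mapsB = NULL) {
  stopifnot(inherits(fitA, "sdm_fit"), inherits(fitB, "sdm_fit"))
  shared <- intersect(fitA$coefficients$term, fitB$coefficients$term)
  a <- fitA$coefficients[match(shared, fitA$coefficients$term), ]
  b <- fitB$coefficients[match(shared, fitB$coefficients$term), ]
  notes <- character(0)
  cc <- if (length(shared) >= 2 && stats::sd(a$mean) > 0 && stats::sd(b$mean) > 0)
    stats::cor(a$mean, b$mean) else { notes <- c(notes,
      "coefficient correlation undefined (fewer than 2 varying coefficients)"); NA_real_ }
  tab <- data.frame(term = shared, mean_A = a$mean, sd_A = a$sd,
                    mean_B = b$mean, sd_B = b$sd)
  mc <- NULL
  if (!is.null(mapsA) && !is.null(mapsB)) {
    gA <- mapsA$log_odds$grid; gB <- mapsB$log_odds$grid
    if (!isTRUE(all.equal(gA[c("origin", "cell_size", "nx", "ny")],
                          gB[c("origin", "cell_size", "nx", "ny")])))
      stop("maps are on different grids")
    all_A <- c(list(log_odds = mapsA$log_odds,
                    probability = mapsA$probability), mapsA$covariates)
    all_B <- c(list(log_odds = mapsB$log_odds,
                    probability = mapsB$probability), mapsB$covariates)
    mc <- sapply(names(all_A), function(nm) {
      x <- all_A[[nm]]$mean; y <- all_B[[nm]]$mean
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        notes <<- c(notes, paste0("map correlation undefined for ", nm,
                                  " (constant or empty map)"))
        NA_real_
      } else stats::cor(x[ok], y[ok])
    })
  }
  list(coefficient_correlation = cc, coefficients = tab,
       map_correlations = mc, notes = notes)
}
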