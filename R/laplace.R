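# Latent-Gaussian logistic model engine.
#
# Model: y_i ~ Bernoulli(plogis(eta_i)) with
#   eta = Xf %*% beta + sum_k B_k u_k + sum_j b_j * v_j
# where beta ~ N(0, diag(Vb)), u_k ~ N(0, C_k) (smooth/spatial components with
# Gaussian covariance), and v_j ~ N(m_j, C_j) are latent errors-in-variables
# covariate values. The coefficients b_j of the latent covariates are FIXED
# here (they are treated as hyperparameters by the callers, which keeps the
# latent problem strictly log-concave; putting them inside the Gaussian
# vector creates a degenerate overfitting mode of the joint MAP where |b|
# grows without bound while the latent values shrink).
#
# Inference is a Laplace approximation found by iteratively reweighted least
# squares. All solves are pushed through the Woodbury identity so the only
# factorizations are n_obs x n_obs and the prior covariances are never
# inverted: with A = d(eta)/d(u) and P0 the blockdiagonal prior covariance,
#   mode update: u* = m0 + P0 A' w,  w = (A P0 A' + D^-1)^-1 (s/D + A(u_c - m0))
#   log|H| - log|P0^-1| = log|D| + log|D^-1 + A P0 A'|.
# The model is linear in the latent vector, so the Gauss-Newton Hessian is
# the exact Hessian and the objective is concave; backtracking is a safety
# net only.

lgm_clip_d <- 1e-10

#' Bernoulli log-likelihood at linear predictor eta
#' @noRd
bern_loglik <- function(y, eta) {
  sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

#' Fit the Laplace approximation of a latent-Gaussian logistic model
#'
#' @param y 0/1 response vector (length n).
#' @param Xf fixed-effect design (n x p).
#' @param Vb prior variances of the fixed effects (length p).
#' @param smooth list of components `list(B = incidence or NULL for identity,
#'   C = prior covariance)`.
#' @param eiv list of components `list(b = fixed coefficient, m = prior mean
#'   (length n), C = prior covariance (n x n))`.
#' @param control list(maxit, tol).
#' @param start optional dual state from a previous fit (warm start).
#' @return list with the mode, conditional posterior of beta, the Laplace
#'   log marginal likelihood, and hooks for sampling.
#' @noRd
lgm_laplace <- function(y, Xf, Vb, smooth = list(), eiv = list(),
                        control = list(), start = NULL) {
  n <- length(y); p <- ncol(Xf)
  maxit <- control$maxit %||% 50
  tol <- control$tol %||% 1e-9
  # observation-space Gram matrix A P0 A' (constant: the model is linear)
  M <- tcrossprod(sweep(Xf, 2, Vb, "*"), Xf)
  for (sm in smooth)
    M <- M + if (is.null(sm$B)) sm$C else sm$B %*% sm$C %*% t(sm$B)
  for (e in eiv) M <- M + (e$b * e$b) * e$C
  eta_offset <- numeric(n)
  for (e in eiv) eta_offset <- eta_offset + e$b * e$m
  realize <- function(cs) {
    st <- list(beta = Vb * cs$cb)
    st$u <- lapply(seq_along(smooth), function(k)
      as.vector(smooth[[k]]$C %*% cs$cu[[k]]))
    st$v <- lapply(seq_along(eiv), function(j)
      eiv[[j]]$m + as.vector(eiv[[j]]$C %*% cs$cv[[j]]))
    st
  }
  eta_of <- function(st) {
    eta <- as.vector(Xf %*% st$beta)
    for (k in seq_along(smooth)) {
      B <- smooth[[k]]$B
      eta <- eta + if (is.null(B)) st$u[[k]] else as.vector(B %*% st$u[[k]])
    }
    for (j in seq_along(eiv)) eta <- eta + eiv[[j]]$b * st$v[[j]]
    eta
  }
  quad <- function(cs, st) {
    q <- sum(cs$cb * st$beta)
    for (k in seq_along(smooth)) q <- q + sum(cs$cu[[k]] * st$u[[k]])
    for (j in seq_along(eiv)) q <- q + sum(cs$cv[[j]] * (st$v[[j]] - eiv[[j]]$m))
    q
  }
  cs <- start %||% list(cb = numeric(p),
                        cu = lapply(smooth, function(s) numeric(ncol(s$C))),
                        cv = lapply(eiv, function(e) numeric(n)))
  st <- realize(cs)
  eta <- eta_of(st)
  obj <- bern_loglik(y, eta) - 0.5 * quad(cs, st)
  converged <- FALSE; it <- 0L
  S_chol <- NULL; D <- NULL
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    D <- pmax(mu * (1 - mu), lgm_clip_d)
    s <- y - mu
    S_chol <- chol(M + diag(1 / D, n))
    rhs <- s / D + eta - eta_offset    # s/D + A (u_c - m0)
    w <- backsolve(S_chol, forwardsolve(t(S_chol), rhs))
    prop <- list(cb = as.vector(crossprod(Xf, w)),
                 cu = lapply(smooth, function(sm) {
                   if (is.null(sm$B)) w else as.vector(crossprod(sm$B, w))
                 }),
                 cv = lapply(eiv, function(e) e$b * w))
    step <- 1; improved <- FALSE
    for (h in 1:25) {
      cs_t <- list(cb = (1 - step) * cs$cb + step * prop$cb,
                   cu = mapply(function(a, b) (1 - step) * a + step * b,
                               cs$cu, prop$cu, SIMPLIFY = FALSE),
                   cv = mapply(function(a, b) (1 - step) * a + step * b,
                               cs$cv, prop$cv, SIMPLIFY = FALSE))
      st_t <- realize(cs_t)
      eta_t <- eta_of(st_t)
      obj_t <- bern_loglik(y, eta_t) - 0.5 * quad(cs_t, st_t)
      if (is.finite(obj_t) && obj_t >= obj - 1e-12) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    delta <- obj_t - obj
    cs <- cs_t; st <- st_t; eta <- eta_t; obj <- obj_t
    if (abs(delta) < tol * (1 + abs(obj))) { converged <- TRUE; break }
  }
  mu <- stats::plogis(eta)
  D <- pmax(mu * (1 - mu), lgm_clip_d)
  S_chol <- chol(M + diag(1 / D, n))
  logml <- bern_loglik(y, eta) - 0.5 * quad(cs, st) -
    0.5 * (sum(log(D)) + 2 * sum(log(diag(S_chol))))
  XV <- sweep(Xf, 2, Vb, "*")
  half <- forwardsolve(t(S_chol), XV)
  beta_cov <- diag(Vb, p) - crossprod(half)
  list(beta = st$beta, beta_cov = beta_cov, state = st, dual = cs,
       eta = eta, mu = mu, D = D, S_chol = S_chol, logml = logml,
       converged = converged, iterations = it,
       mod = list(Xf = Xf, Vb = Vb, smooth = smooth, eiv = eiv), y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from the Laplace posterior of all latent components (Matheron's rule)
#'
#' @param fit output of lgm_laplace.
#' @param n number of draws.
#' @param chol_cache optional precomputed Cholesky factors of the component
#'   prior covariances (list with `smooth`, `eiv` entries).
#' @return list(beta = p x n, u = list of q_k x n, v = list of n_obs x n)
#' @noRd
lgm_draws <- function(fit, n, chol_cache = NULL) {
  mod <- fit$mod; st <- fit$state
  nobs <- length(fit$y); p <- length(st$beta)
  Ls <- chol_cache$smooth %||% lapply(mod$smooth, function(s) chol_cov(s$C))
  Le <- chol_cache$eiv %||% lapply(mod$eiv, function(e) chol_cov(e$C))
  beta_d <- matrix(0, p, n)
  u_d <- lapply(mod$smooth, function(s) matrix(0, ncol(s$C), n))
  v_d <- lapply(mod$eiv, function(e) matrix(0, nobs, n))
  for (i in seq_len(n)) {
    b0 <- stats::rnorm(p, 0, sqrt(mod$Vb))
    u0 <- lapply(Ls, function(L) as.vector(crossprod(L, stats::rnorm(ncol(L)))))
    v0 <- lapply(Le, function(L) as.vector(crossprod(L, stats::rnorm(ncol(L)))))
    Au <- as.vector(mod$Xf %*% b0)
    for (k in seq_along(mod$smooth)) {
      B <- mod$smooth[[k]]$B
      Au <- Au + if (is.null(B)) u0[[k]] else as.vector(B %*% u0[[k]])
    }
    for (j in seq_along(mod$eiv)) Au <- Au + mod$eiv[[j]]$b * v0[[j]]
    e <- stats::rnorm(nobs, 0, sqrt(1 / fit$D))
    w <- backsolve(fit$S_chol, forwardsolve(t(fit$S_chol), Au + e))
    beta_d[, i] <- st$beta + b0 - mod$Vb * as.vector(crossprod(mod$Xf, w))
    for (k in seq_along(mod$smooth)) {
      B <- mod$smooth[[k]]$B
      cw <- if (is.null(B)) w else as.vector(crossprod(B, w))
      u_d[[k]][, i] <- st$u[[k]] + u0[[k]] - as.vector(mod$smooth[[k]]$C %*% cw)
    }
    for (j in seq_along(mod$eiv)) {
      v_d[[j]][, i] <- st$v[[j]] + v0[[j]] -
        as.vector(mod$eiv[[j]]$C %*% (mod$eiv[[j]]$b * w))
    }
  }
  list(beta = beta_d, u = u_d, v = v_d)
}

# ---------------------------------------------------------------------------
# Hyperparameter layer: maximize a Laplace/exact log posterior over a small
# vector of hyperparameters, approximate its curvature by finite differences,
# and return a deterministic set of exploration points with normalized
# weights (mode plus one point either side along each principal curvature
# axis). Posterior summaries downstream are mixtures over these points,
# which propagates hyperparameter uncertainty by deterministic nested
# integration.
# ---------------------------------------------------------------------------

#' @noRd
hyper_explore <- function(logpost, init, step = 1.1, maxit = 120,
                          reltol = 1e-5, lower = -25, upper = 25,
                          fd_h = 0.07, restarts = 2, fd_pairs = NULL) {
  k <- length(init)
  clampfn <- function(th) pmin(pmax(th, lower), upper)
  negf <- function(th) -logpost(clampfn(th))
  opt <- if (k == 1) {
    stats::optim(init, negf, method = "Brent", lower = lower, upper = upper,
                 control = list(maxit = maxit))
  } else {
    stats::optim(init, negf, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  }
  mode <- clampfn(opt$par)
  f0 <- -opt$value
  h <- fd_h
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (logpost(clampfn(mode + ei)) - 2 * f0 +
                  logpost(clampfn(mode - ei))) / h^2
  }
  if (k > 1) {
    pairs <- fd_pairs %||% {
      p <- list()
      for (i in 1:(k - 1)) for (j in (i + 1):k) p[[length(p) + 1]] <- c(i, j)
      p
    }
    for (pp in pairs) {
      i <- pp[1]; j <- pp[2]
      eij <- replace(numeric(k), c(i, j), h)
      eimj <- replace(replace(numeric(k), i, h), j, -h)
      H[i, j] <- H[j, i] <-
        (logpost(clampfn(mode + eij)) + logpost(clampfn(mode - eij)) -
           logpost(clampfn(mode + eimj)) - logpost(clampfn(mode - eimj))) /
        (4 * h^2)
    }
  }
  ev <- eigen(-H, symmetric = TRUE)
  # floor curvature so flat directions (e.g. a noise variance pinned at zero)
  # do not produce unbounded exploration steps
  lam <- pmax(ev$values, (step / 1.5)^-2)
  sd_dir <- sweep(ev$vectors, 2, 1 / sqrt(lam), "*")
  pts <- list(mode)
  for (i in seq_len(k)) {
    pts[[length(pts) + 1]] <- clampfn(mode + step * sd_dir[, i])
    pts[[length(pts) + 1]] <- clampfn(mode - step * sd_dir[, i])
  }
  lp <- c(f0, vapply(pts[-1], logpost, numeric(1)))
  # safeguard: if the exploration finds a clearly better point the optimizer
  # stopped short of the mode; restart from there
  if (restarts > 0 && max(lp) > f0 + 0.2) {
    return(hyper_explore(logpost, pts[[which.max(lp)]], step = step,
                         maxit = maxit, reltol = reltol, lower = lower,
                         upper = upper, fd_h = fd_h, restarts = restarts - 1,
                         fd_pairs = fd_pairs))
  }
  wt <- exp(lp - max(lp)); wt <- wt / sum(wt)
  prec <- ev$vectors %*% diag(lam, k) %*% t(ev$vectors)
  list(mode = mode, logpost_mode = f0, points = pts, weights = wt,
       logpost_points = lp,
       precision = prec, cov = solve(prec), converged = opt$convergence == 0,
       optim_convergence = opt$convergence)
}

#' Moment-match a mixture of Gaussian summaries into mean/sd tables
#' means: k x npts matrix, vars: k x npts matrix, weights length npts
#' @noRd
mix_moments <- function(means, vars, weights) {
  m <- as.vector(means %*% weights)
  v <- as.vector(vars %*% weights) + as.vector((means^2) %*% weights) - m^2
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Summary table on the original (exponentiated) scale for log-scale
#' hyperparameters explored by hyper_explore: lognormal moment summaries
#' mixed over exploration points.
#' @noRd
hyper_summary_table <- function(hx, names_log, idx = seq_along(names_log)) {
  rows <- lapply(seq_along(idx), function(ii) {
    i <- idx[ii]
    mus <- vapply(hx$points, function(p) p[i], numeric(1))
    # mean from the weighted exploration points (captures mild skewness);
    # spread from the Gaussian curvature approximation
    m_log <- sum(hx$weights * mus)
    v_log <- pmax(hx$cov[i, i], 0)
    mean_nat <- exp(m_log + v_log / 2)
    sd_nat <- mean_nat * sqrt(pmax(exp(v_log) - 1, 0))
    data.frame(parameter = names_log[ii],
               mean = mean_nat, sd = sd_nat,
               q2.5 = exp(m_log - 1.96 * sqrt(v_log)),
               q97.5 = exp(m_log + 1.96 * sqrt(v_log)))
  })
  do.call(rbind, rows)
}

#' Mixture mean/sd of an untransformed hyperparameter coordinate
#' @noRd
hyper_coord_moments <- function(hx, i) {
  mus <- vapply(hx$points, function(p) p[i], numeric(1))
  m <- sum(hx$weights * mus)
  c(mean = m, sd = sqrt(pmax(hx$cov[i, i], 0)))
}
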