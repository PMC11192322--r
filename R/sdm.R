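#' Species presence/absence observations
#'
#' @param points point set of field-visit locations.
#' @param y binary 0/1 presence/absence vector, one per location.
#' @param covariates optional data frame of covariate values observed at the
#'   same locations (columns named; NA where a covariate was not measured).
#' @return Object of class `species_observations`.
#' @export
species_observations <- function(points, y, covariates = NULL) {
  points <- as_points(points)
  y <- as.numeric(y)
  if (length(y) != nrow(points)) stop("one response per location required")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(points))
      stop("covariate table must have one row per location")
  }
  structure(list(points = points, y = y, covariates = covariates),
            class = "species_observations")
}

#' @export
print.species_observations <- function(x, ...) {
  cat(sprintf("species_observations: %d visits, prevalence %.3f, covariates: %s\n",
              length(x$y), mean(x$y),
              if (is.null(x$covariates)) "none" else
                paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Structure of the species distribution model
#'
#' Declares the additive predictor
#' eta_i = beta0 + sum_j beta_j x_j(s_i) + sum_l f_l(z_l(s_i)) + W(s_i):
#' named covariates with linear effects, named covariates entering through
#' second-order random-walk splines over a binned domain, and an optional
#' Matern spatial residual W absorbing leftover spatial pattern.
#'
#' Each spline is constrained to sum to zero across bins for identifiability
#' against the intercept; its (unpenalized) linear trend is kept as an
#' explicit vague-prior coefficient, so the constraint costs no flexibility.
#'
#' @param linear character vector of covariate names with linear effects.
#' @param splines character vector of covariate names with RW2 spline effects.
#' @param spline_bins number of equal-width bins per spline (>= 4; default 20).
#' @param spatial logical; include the spatial residual W(s)?
#' @param intercept logical; include beta0?
#' @param priors a [prior_config()].
#' @return Object of class `sdm_spec`.
#' @export
sdm_spec <- function(linear = character(), splines = character(),
                     spline_bins = 20L, spatial = TRUE, intercept = TRUE,
                     priors = prior_config()) {
  if (spline_bins < 4) stop("spline_bins must be >= 4")
  if (length(linear) + length(splines) < 1 && !spatial && !intercept)
    stop("model needs at least one of: a covariate term, the spatial ",
         "residual, or an intercept")
  structure(list(linear = linear, splines = splines,
                 spline_bins = as.integer(spline_bins),
                 spatial = isTRUE(spatial), intercept = isTRUE(intercept),
                 priors = priors),
            class = "sdm_spec")
}

#' Logistic link
#'
#' mu = 1 / (1 + exp(-eta)); strictly increasing, mu(0) = 0.5,
#' mu(eta) + mu(-eta) = 1.
#' @param eta real vector.
#' @return probabilities in (0, 1).
#' @export
logistic_link <- function(eta) stats::plogis(eta)

#' Evaluate the additive predictor for explicit parameter values
#'
#' Pure arithmetic: `eta_i = beta0 + sum_j beta_j * covariates[[j]] +
#' sum_l spline_values[[l]] + W_i`. Useful for constructing ground truth and
#' for checking fitted models; no estimation happens here.
#'
#' @param spec an [sdm_spec()].
#' @param params list with `beta0` (scalar), `beta` (named vector over
#'   `spec$linear`), `spline_values` (named list of per-observation spline
#'   contributions over `spec$splines`), `W` (per-observation vector or NULL).
#' @param covariates data frame holding every column named in `spec$linear`.
#' @return Numeric vector eta.
#' @export
linear_predictor <- function(spec, params, covariates) {
  stopifnot(inherits(spec, "sdm_spec"))
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  eta <- rep(if (spec$intercept) params$beta0 else 0, n)
  for (nm in spec$linear) {
    if (!nm %in% names(covariates))
      stop("missing covariate column: ", nm)
    eta <- eta + params$beta[[nm]] * covariates[[nm]]
  }
  for (nm in spec$splines) {
    sv <- params$spline_values[[nm]]
    if (is.null(sv)) stop("missing spline values for: ", nm)
    eta <- eta + sv
  }
  if (!is.null(params$W)) eta <- eta + params$W
  eta
}

#' Log-density of a second-order random-walk spline (up to a constant)
#'
#' Sums log N(u_i - 2 u_{i+1} + u_{i+2}; 0, zeta^2) over the d - 2 interior
#' triples of the ordered bin values u. Adding any linear function of the bin
#' index leaves the density unchanged (the RW2 null space), which is why
#' fitted splines carry an explicit identifiability constraint.
#'
#' @param u spline values over d >= 4 ordered bins.
#' @param zeta2 increment variance > 0.
#' @return log-density (constant terms from the Gaussian included).
#' @export
rw2_log_density <- function(u, zeta2) {
  if (length(u) < 4) stop("need at least 4 bins")
  if (!is.numeric(zeta2) || zeta2 <= 0) stop("zeta2 must be > 0")
  d2 <- diff(u, differences = 2)
  sum(stats::dnorm(d2, 0, sqrt(zeta2), log = TRUE))
}

#' Discretize a covariate into equal-width bins
#'
#' Bins span the observed range; every observation is assigned to exactly one
#' bin (the maximum falls in the last bin). Midpoints support plotting fitted
#' spline curves.
#'
#' @param values numeric covariate vector (non-degenerate).
#' @param d number of bins (>= 4).
#' @return list(assignment = integer bin per value, midpoints = length-d
#'   vector, edges = length-(d+1) vector).
#' @export
bin_covariate <- function(values, d) {
  if (d < 4) stop("need at least 4 bins")
  r <- range(values, na.rm = TRUE)
  if (!all(is.finite(r)) || diff(r) == 0)
    stop("covariate is constant; remove its spline term")
  edges <- seq(r[1], r[2], length.out = d + 1)
  a <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(assignment = as.integer(a),
       midpoints = (edges[-1] + edges[-(d + 1)]) / 2,
       edges = edges)
}

# ---------------------------------------------------------------------------
# RW2 spline basis for the latent-Gaussian engine.
#
# The improper RW2 prior over d bin values has penalty P = t(D2) %*% D2
# (D2 the second-difference operator) with null space {1, index}. We make it
# proper by splitting f = T g + L v: T is the centred, unit-scaled linear
# trend (vague N(0, Vb) coefficient g), L = V+ %*% diag(1/sqrt(lambda+)) from
# the positive eigenpairs of P so that v ~ N(0, zeta2 I) reproduces the RW2
# increment density on the penalized subspace, and the constant is dropped
# (sum-to-zero constraint). Columns of L are orthogonal to 1, so any fitted
# spline sums to zero across bins by construction.
# ---------------------------------------------------------------------------
rw2_basis <- function(d) {
  D2 <- diff(diag(d), differences = 2)
  P <- crossprod(D2)
  e <- eigen(P, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-9
  L <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  idx <- seq_len(d) - (d + 1) / 2
  Tlin <- idx / sqrt(sum(idx^2))
  list(L = L, T = Tlin)
}
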