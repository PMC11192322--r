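#' Point sets
#'
#' A point set is a data frame with numeric columns `x` and `y` giving planar
#' coordinates. Coordinates are unit-agnostic (km for projected national data,
#' unit-square coordinates for simulations); distances are Euclidean in the
#' units supplied.
#'
#' @param x,y numeric vectors of equal length; must be finite.
#' @return A data frame of class `points` with columns `x`, `y`.
#' @export
points_df <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("point coordinates must be finite")
  structure(data.frame(x = x, y = y), class = c("points", "data.frame"))
}

as_points <- function(p) {
  if (is.matrix(p)) p <- as.data.frame(p)
  if (!all(c("x", "y") %in% names(p))) stop("point set needs columns x and y")
  points_df(p$x, p$y)
}

#' Euclidean distance matrix between two point sets
#' @noRd
cross_dist <- function(p, q) {
  dx <- outer(p$x, q$x, "-")
  dy <- outer(p$y, q$y, "-")
  sqrt(dx * dx + dy * dy)
}

#' Matern covariance parameters (smoothness fixed at 1)
#'
#' Parameters of a stationary Matern covariance with smoothness nu = 1:
#' marginal variance (partial sill) sigma^2 and range r. The range is the
#' distance at which the spatial correlation has decayed to approximately 0.14,
#' i.e. close to zero; internally the Matern scale parameter is
#' kappa = sqrt(8) / range, the standard relation for nu = 1.
#'
#' @param variance marginal variance sigma^2 > 0.
#' @param range spatial range r > 0, in the distance units of the point set.
#' @param smoothness must be 1; other values are rejected.
#' @return An object of class `matern_params`.
#' @export
matern_params <- function(variance, range, smoothness = 1) {
  if (!is.numeric(variance) || length(variance) != 1 || !is.finite(variance) || variance <= 0)
    stop("variance must be a positive number")
  if (!is.numeric(range) || length(range) != 1 || !is.finite(range) || range <= 0)
    stop("range must be a positive number")
  if (!identical(as.numeric(smoothness), 1))
    stop("only smoothness nu = 1 is supported")
  structure(list(variance = variance, range = range, smoothness = 1),
            class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("Matern(nu = 1): variance = %g, range = %g\n", x$variance, x$range))
  invisible(x)
}

#' Matern correlation function (nu = 1)
#'
#' Correlation at distance `d` of a Matern field with smoothness 1:
#' rho(d) = (kappa d) K_1(kappa d) with kappa = sqrt(8)/range, where K_1 is the
#' modified Bessel function of the second kind. rho(0) = 1 (limit) and
#' rho(range) is approximately 0.14, so the range is the distance at which
#' correlation is close to zero.
#'
#' @param d non-negative distances (vector ok).
#' @param range spatial range > 0.
#' @return Correlations in (0, 1], same length as `d`.
#' @export
matern_correlation <- function(d, range) {
  if (!is.numeric(range) || length(range) != 1 || !is.finite(range) || range <= 0)
    stop("range must be a positive number")
  if (any(d < 0)) stop("distances must be non-negative")
  kd <- (sqrt(8) / range) * d
  out <- numeric(length(kd))
  mid <- kd > 0 & kd < 40
  out[mid] <- matern_g()(kd[mid])
  out[kd == 0] <- 1
  # correlation underflows to 0 beyond kd = 40 (< 1e-16); that is the limit
  out
}

# cubic-spline interpolant of g(x) = x K_1(x) on (0, 40], built once per
# session; absolute error < 1e-10, far below the covariance jitter
matern_g_env <- new.env(parent = emptyenv())
matern_g <- function() {
  if (is.null(matern_g_env$fun)) {
    x <- c(seq(1e-7, 0.1, length.out = 20000),
           seq(0.1 + 1e-5, 1, length.out = 20000),
           seq(1 + 1e-4, 5, length.out = 16000),
           seq(5 + 1e-3, 40, length.out = 16000))
    matern_g_env$fun <- stats::splinefun(x, x * besselK(x, nu = 1),
                                         method = "natural")
  }
  matern_g_env$fun
}

#' Matern covariance matrix over a point set
#'
#' Entry (i, j) is variance * matern_correlation(distance(i, j), range).
#' Duplicate points are allowed and give identical rows; the matrix is
#' symmetric with the variance on the diagonal and is positive semi-definite
#' up to floating-point error.
#'
#' @param points a point set (data frame with x, y).
#' @param params a [matern_params()] object.
#' @return A symmetric covariance matrix.
#' @export
matern_covariance_matrix <- function(points, params) {
  points <- as_points(points)
  if (nrow(points) < 1) stop("need at least one point")
  stopifnot(inherits(params, "matern_params"))
  D <- cross_dist(points, points)
  C <- params$variance * matern_correlation(as.vector(D), params$range)
  matrix(C, nrow(points), nrow(points))
}

#' Cross-covariance between two point sets under a Matern model
#' @noRd
matern_cross_cov <- function(p, q, params) {
  D <- cross_dist(as_points(p), as_points(q))
  matrix(params$variance * matern_correlation(as.vector(D), params$range),
         nrow(D), ncol(D))
}

# Jitter policy: add 1e-8 * variance to the diagonal before factorization.
matern_jitter <- 1e-8

#' Cholesky with the package jitter policy
#' @noRd
chol_cov <- function(C, scale = mean(diag(C))) {
  C <- C + diag(matern_jitter * scale, nrow(C))
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(out))
    stop("covariance matrix not positive definite even after jitter; ",
         "check for extreme parameter values or coincident points")
  out
}

#' A realization of a random field at a point set
#'
#' @param points point set where the field was evaluated.
#' @param values numeric vector, one value per point.
#' @param seed integer seed used to generate the values (NA if not simulated).
#' @return Object of class `field_realization`.
#' @export
field_realization <- function(points, values, seed = NA_integer_) {
  points <- as_points(points)
  values <- as.numeric(values)
  if (length(values) != nrow(points))
    stop("need exactly one value per point")
  structure(list(points = points, values = values, seed = seed),
            class = "field_realization")
}

#' @export
print.field_realization <- function(x, ...) {
  cat(sprintf("field_realization: %d points, value range [%.3g, %.3g]\n",
              nrow(x$points), min(x$values), max(x$values)))
  invisible(x)
}

#' Simulate a zero-mean Matern Gaussian random field
#'
#' Draws from MVN(0, Sigma(variance, range)) at the supplied points by dense
#' Cholesky factorization. Reproducible given the seed.
#'
#' @param points point set.
#' @param params [matern_params()].
#' @param seed integer seed.
#' @param n number of independent realizations (default 1).
#' @return A `field_realization` if `n = 1`, else a list of them (sharing the
#'   Cholesky factor, with values drawn sequentially from the seeded stream).
#' @export
simulate_grf <- function(points, params, seed, n = 1) {
  points <- as_points(points)
  L <- chol_cov(matern_covariance_matrix(points, params), scale = params$variance)
  m <- nrow(points)
  draws <- with_seed(seed, matrix(stats::rnorm(m * n), m, n))
  vals <- crossprod(L, draws) # t(L) %*% z, L upper triangular from chol()
  if (n == 1) return(field_realization(points, vals[, 1], seed))
  lapply(seq_len(n), function(j) field_realization(points, vals[, j], seed))
}

#' Build a confounded covariate pair from three shared-variance field draws
#'
#' Given three independent realizations z, z1, z2 of a Gaussian field with
#' variance 0.5 on the same point set, returns x1 = z + z1 and x2 = z + z2.
#' The shared component makes the covariates spatially autocorrelated and
#' confounded: Var(x1) = Var(x2) = 1 and Cov(x1, x2) = 0.5.
#'
#' @param z,z1,z2 `field_realization` objects on an identical point set.
#' @return List with elements `x1`, `x2` (field_realization).
#' @export
make_confounded_pair <- function(z, z1, z2) {
  for (f in list(z, z1, z2)) stopifnot(inherits(f, "field_realization"))
  if (!isTRUE(all.equal(z$points, z1$points, check.attributes = FALSE)) ||
      !isTRUE(all.equal(z$points, z2$points, check.attributes = FALSE)))
    stop("all three realizations must share the same point set")
  list(x1 = field_realization(z$points, z$values + z1$values, z$seed),
       x2 = field_realization(z$points, z$values + z2$values, z$seed))
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.na(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

#' Derive a stream of child seeds from a master seed
#' @noRd
child_seeds <- function(seed, n, salt = 0L) {
  # splitmix-style integer hash, keeps everything below 2^31
  s <- as.double(seed) + as.double(salt) * 7919
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 69069 + 1234567) %% 2147483647
    out[i] <- floor(s)
  }
  as.integer(out)
}

#' Write / read a field realization as CSV (columns x, y, value)
#' @param f a `field_realization`.
#' @param path file path.
#' @return `read_field_csv` returns a `field_realization`.
#' @export
write_field_csv <- function(f, path) {
  stopifnot(inherits(f, "field_realization"))
  utils::write.csv(data.frame(x = f$points$x, y = f$points$y, value = f$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y", "value") %in% names(d)))
    stop("field CSV needs columns x, y, value")
  field_realization(points_df(d$x, d$y), d$value)
}
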