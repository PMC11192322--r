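# Matern correlation, covariance matrices, GRF simulation, and the
# confounded covariate construction.

test_that("Matern (nu = 1) correlation matches the Bessel oracle and decays", {
  expect_equal(matern_correlation(0, 0.3), 1)
  # sqrt(8) * K_1(sqrt(8)), frozen from an independent high-precision Bessel
  # evaluation: the correlation at d = range is ~0.14, "close to zero"
  expect_equal(matern_correlation(0.3, 0.3), 0.1396674740152931,
               tolerance = 1e-8)
  expect_equal(matern_correlation(1.7, 1.7), 0.1396674740152931,
               tolerance = 1e-8)
  d <- seq(0.01, 3, by = 0.01)
  rho <- matern_correlation(d, 0.3)
  expect_true(all(diff(rho) < 0))           # strictly decreasing
  expect_true(all(rho > 0 & rho <= 1))
  expect_lt(matern_correlation(20 * 0.3, 0.3), 1e-6)  # effective zero
  expect_error(matern_correlation(0.1, -1), "range")
  expect_error(matern_correlation(-0.1, 1), "non-negative")
})

test_that("parameter validation rejects bad Matern parameters", {
  expect_error(matern_params(-1, 0.3), "variance")
  expect_error(matern_params(1, 0), "range")
  expect_error(matern_params(1, 0.3, smoothness = 2), "smoothness")
  expect_error(points_df(c(1, NaN), c(1, 2)), "finite")
})

test_that("covariance matrix is symmetric PSD with sigma2 diagonal", {
  p <- matern_params(0.5, 0.3)
  for (seed in 1:3) {
    pts <- unit_points(sample(5:200, 1), seed)
    C <- matern_covariance_matrix(pts, p)
    expect_equal(diag(C), rep(0.5, nrow(pts)))
    expect_equal(C, t(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  # two points at distance 0.3 with sigma2 = 0.5: off-diagonal = 0.5 * rho
  C2 <- matern_covariance_matrix(points_df(c(0, 0.3), c(0, 0)), p)
  expect_equal(C2[1, 2], 0.5 * 0.1396674740152931, tolerance = 1e-8)
  # duplicate points allowed, identical rows
  C3 <- matern_covariance_matrix(points_df(c(0, 0, 1), c(0, 0, 1)), p)
  expect_equal(C3[1, ], C3[2, ])
})

test_that("simulate_grf is seed-reproducible with correct moments", {
  p <- matern_params(0.5, 0.3)
  pts <- unit_points(300, 2)
  a <- simulate_grf(pts, p, seed = 7)
  b <- simulate_grf(pts, p, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, simulate_grf(pts, p, seed = 8)$values))
  # pooled moments over replicates: mean -> 0, variance -> sigma2. The
  # process mean is known to be zero, so raw second moments are used:
  # centering each realization at its own spatial average removes real
  # variance when the field is correlated.
  reps <- simulate_grf(pts, p, seed = 9, n = 200)
  vals <- vapply(reps, function(f) f$values, numeric(300))
  expect_equal(mean(vals), 0, tolerance = 3 * sqrt(0.5 / 200) * 2)
  expect_equal(mean(vals^2), 0.5, tolerance = 0.05)
  # binned empirical correlation follows the Matern curve
  Dm <- as.matrix(dist(cbind(pts$x, pts$y)))
  emp_cov <- tcrossprod(vals) / ncol(vals)
  bins <- cut(as.vector(Dm), breaks = seq(0, 0.6, by = 0.1))
  emp <- tapply(as.vector(emp_cov) / 0.5, bins, mean)
  dmid <- seq(0.05, 0.55, by = 0.1)
  expect_lt(max(abs(emp - matern_correlation(dmid, 0.3))), 0.12)
})

test_that("confounded pair has variance 1, covariance 0.5, correlation 0.5", {
  p <- matern_params(0.5, 0.3)
  pts <- unit_points(400, 4)
  # zero fields give zero covariates
  z0 <- field_realization(pts, numeric(400))
  cp0 <- make_confounded_pair(z0, z0, z0)
  expect_equal(cp0$x1$values, numeric(400))
  # elementwise sums
  z <- simulate_grf(pts, p, 1); z1 <- simulate_grf(pts, p, 2)
  z2 <- simulate_grf(pts, p, 3)
  cp <- make_confounded_pair(z, z1, z2)
  expect_equal(cp$x1$values, z$values + z1$values)
  # large-sample moments pooled over replicates, using the known zero mean
  v1 <- v2 <- cv <- numeric(30)
  for (r in 1:30) {
    zz <- lapply(1:3, function(k) simulate_grf(pts, p, 100 * r + k))
    cp <- make_confounded_pair(zz[[1]], zz[[2]], zz[[3]])
    v1[r] <- mean(cp$x1$values^2); v2[r] <- mean(cp$x2$values^2)
    cv[r] <- mean(cp$x1$values * cp$x2$values)
  }
  expect_equal(mean(v1), 1.0, tolerance = 0.12)
  expect_equal(mean(v2), 1.0, tolerance = 0.12)
  expect_equal(mean(cv), 0.5, tolerance = 0.1)
  expect_equal(mean(cv) / sqrt(mean(v1) * mean(v2)), 0.5, tolerance = 0.1)
  # mismatched point sets rejected
  other <- simulate_grf(unit_points(400, 9), p, 4)
  expect_error(make_confounded_pair(z, z1, other), "point set")
})

test_that("field realizations round-trip through CSV", {
  f <- simulate_grf(unit_points(25, 5), matern_params(1, 0.5), 11)
  path <- tempfile(fileext = ".csv")
  write_field_csv(f, path)
  g <- read_field_csv(path)
  expect_equal(g$points$x, f$points$x)
  expect_equal(g$values, f$values)
})
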