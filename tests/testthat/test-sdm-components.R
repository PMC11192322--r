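# Additive predictor, logistic link, RW2 spline density, covariate binning,
# and the spline basis identifiability constraints.

test_that("logistic link values and symmetry", {
  expect_equal(logistic_link(0), 0.5)
  expect_equal(logistic_link(-2), 1 / (1 + exp(2)))  # ~0.1192
  eta <- rnorm(50, sd = 3)
  expect_equal(logistic_link(eta) + logistic_link(-eta), rep(1, 50))
  expect_true(all(diff(logistic_link(seq(-5, 5, 0.1))) > 0))
})

test_that("linear predictor is plain accumulation over terms", {
  spec <- sdm_spec(linear = c("x1", "x2"), spatial = TRUE)
  n <- 20
  covs <- data.frame(x1 = rep(1, n), x2 = rep(1, n))
  pars <- list(beta0 = -2, beta = c(x1 = 1, x2 = 1), W = rep(0, n))
  expect_equal(linear_predictor(spec, pars, covs), rep(0, n))
  # all zero except intercept
  covs0 <- data.frame(x1 = rep(0, n), x2 = rep(0, n))
  expect_equal(linear_predictor(spec, pars, covs0), rep(-2, n))
  # random instance against a term-by-term oracle
  set.seed(8)
  covs_r <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  W <- rnorm(n)
  pars_r <- list(beta0 = 0.4, beta = c(x1 = -1.2, x2 = 0.7), W = W)
  oracle <- 0.4 + -1.2 * covs_r$x1 + 0.7 * covs_r$x2 + W
  expect_equal(linear_predictor(spec, pars_r, covs_r), oracle)
  # additivity: eta(T1 union T2) = eta(T1) + eta(T2) - beta0
  s1 <- sdm_spec(linear = "x1", spatial = FALSE)
  s2 <- sdm_spec(linear = "x2", spatial = FALSE)
  p1 <- list(beta0 = 0.4, beta = c(x1 = -1.2))
  p2 <- list(beta0 = 0.4, beta = c(x2 = 0.7))
  both <- sdm_spec(linear = c("x1", "x2"), spatial = FALSE)
  pb <- list(beta0 = 0.4, beta = c(x1 = -1.2, x2 = 0.7))
  expect_equal(linear_predictor(both, pb, covs_r),
               linear_predictor(s1, p1, covs_r) +
                 linear_predictor(s2, p2, covs_r) - 0.4)
  expect_error(linear_predictor(spec, pars, covs_r[, "x1", drop = FALSE]),
               "x2")
})

test_that("RW2 log-density penalizes curvature and ignores linear trends", {
  # linear in bin index: all second differences vanish, maximal density
  u_lin <- 2.5 * (1:8) + 1
  expect_equal(rw2_log_density(u_lin, 0.5),
               6 * dnorm(0, 0, sqrt(0.5), log = TRUE))
  # quadratic on 5 bins: three interior triples, each with delta2 = 2
  u_sq <- (1:5)^2
  expect_equal(rw2_log_density(u_sq, 0.7),
               3 * dnorm(2, 0, sqrt(0.7), log = TRUE))
  # invariance to adding c * index + b, machine precision, random u
  for (seed in 1:5) {
    set.seed(seed)
    u <- rnorm(12); cc <- rnorm(1); b <- rnorm(1)
    expect_equal(rw2_log_density(u + cc * (1:12) + b, 0.3),
                 rw2_log_density(u, 0.3), tolerance = 1e-12)
  }
  expect_error(rw2_log_density(1:3, 0.5), "4 bins")
  expect_error(rw2_log_density(1:6, -0.1), "zeta2")
})

test_that("covariate binning partitions the observed range", {
  v <- seq(0, 1, length.out = 101)
  b <- bin_covariate(v, 4)
  expect_equal(b$edges, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(length(b$assignment), 101)
  expect_true(all(b$assignment %in% 1:4))
  expect_equal(as.vector(table(b$assignment)), c(25, 25, 25, 26))
  expect_equal(b$midpoints, c(0.125, 0.375, 0.625, 0.875))
  expect_error(bin_covariate(rep(2, 50), 5), "constant")
})

test_that("spline basis satisfies sum-to-zero and reproduces the RW2 law", {
  bas <- krigsdm:::rw2_basis(12)
  expect_equal(ncol(bas$L), 10)              # d - 2 penalized directions
  expect_lt(max(abs(colSums(bas$L))), 1e-10) # orthogonal to the constant
  expect_lt(abs(sum(bas$T)), 1e-10)          # centred linear trend
  # any f = T g + L v sums to zero across bins
  set.seed(2)
  f <- bas$T * rnorm(1) + as.vector(bas$L %*% rnorm(10))
  expect_lt(abs(sum(f)), 1e-8)
  # the quadratic form v'v equals the RW2 penalty of the realized spline
  v <- rnorm(10)
  f2 <- as.vector(bas$L %*% v)
  penalty <- sum(diff(f2, differences = 2)^2)
  expect_equal(penalty, sum(v^2), tolerance = 1e-8)
})

test_that("a fitted spline recovers a nonlinear shape and sums to zero", {
  set.seed(14)
  n <- 500
  z <- runif(n, -2, 2)
  eta <- -0.5 + 1.2 * sin(z)
  y <- rbinom(n, 1, plogis(eta))
  sp <- species_observations(unit_points(n, 15), y, data.frame(z = z))
  spec <- sdm_spec(splines = "z", spline_bins = 12, spatial = FALSE)
  fit <- fit_direct(sp, spec, test_inference())
  tab <- fit$splines$z
  expect_equal(nrow(tab), 12)
  # identifiability: spline sums to zero across bins (basis-level exact;
  # the tabulated posterior means carry only Monte-Carlo noise)
  expect_lt(abs(sum(tab$mean)), 0.05)
  # shape: increasing then decreasing like sin on (-2, 2)
  expect_gt(cor(tab$mean, sin(tab$bin_midpoint)), 0.8)
})
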