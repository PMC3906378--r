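# Probability functions of every family and flavor: normalization,
# closed-form examples, support handling, discretization schemes.

example_models <- function() {
  list(
    heavy_dist("power_law", 2.5, xmin = 1),
    heavy_dist("power_law", 1.7, xmin = 2, xmax = 500),
    heavy_dist("exponential", 0.5, xmin = 1),
    heavy_dist("exponential", 0.5, xmin = 1, xmax = 30),
    heavy_dist("stretched_exponential", c(0.6, 0.7), xmin = 1),
    heavy_dist("lognormal", c(0.5, 1.1), xmin = 1),
    heavy_dist("lognormal", c(0.5, 1.1), xmin = 2, xmax = 100),
    heavy_dist("truncated_power_law", c(1.8, 0.05), xmin = 1),
    heavy_dist("truncated_power_law", c(1.8, 0.05), xmin = 1, xmax = 80),
    heavy_dist("gamma", c(2, 3), xmin = 1)
  )
}

test_that("continuous densities integrate to one over the support", {
  for (d in example_models()) {
    expect_equal(oracle_integral_pdf(d), 1, tolerance = 1e-6,
                 label = paste("integral of", d$family))
  }
})

test_that("discrete flavors sum to one over the support", {
  models <- list(
    heavy_dist("power_law", 2.5, xmin = 1, discrete = TRUE),
    heavy_dist("power_law", 2.0, xmin = 3, xmax = 500, discrete = TRUE),
    heavy_dist("exponential", 0.3, xmin = 1, discrete = TRUE),
    heavy_dist("lognormal", c(0.5, 1.1), xmin = 1, discrete = TRUE),
    heavy_dist("lognormal", c(0.5, 1.1), xmin = 1, xmax = 300,
               discrete = TRUE, discrete_approximation = "xmax"),
    heavy_dist("stretched_exponential", c(0.6, 0.7), xmin = 1,
               discrete = TRUE),
    heavy_dist("truncated_power_law", c(1.8, 0.05), xmin = 1,
               discrete = TRUE),
    heavy_dist("gamma", c(2, 3), xmin = 1, discrete = TRUE),
    heavy_dist("power_law", 2.0, xmin = 1, discrete = TRUE,
               discrete_approximation = 2000)
  )
  for (d in models) {
    total <- oracle_discrete_mass(d) +
      if (is.null(d$xmax) && !is.numeric(d$discrete_approximation))
        dist_ccdf(d, 2e5) else 0
    expect_equal(total, 1, tolerance = 1e-6,
                 label = paste("mass sum of", d$family,
                               d$discrete_approximation))
  }
})

test_that("power-law closed forms: pdf, ccdf, normalizer", {
  d <- heavy_dist("power_law", 2.5, xmin = 1)
  expect_equal(dist_pdf(d, 1), 1.5)
  expect_equal(dist_ccdf(d, 4), 0.125)
  expect_equal(dist_normalizer(d), 1 / 1.5)
  d2 <- heavy_dist("power_law", 2, xmin = 1, xmax = 2)
  expect_equal(dist_normalizer(d2), 0.5)
  expect_equal(dist_cdf(d2, 2), 1)
  # discrete brute-force normalizer approaches the zeta function
  dz <- heavy_dist("power_law", 2, xmin = 1, discrete = TRUE,
                   discrete_approximation = 1e6)
  expect_equal(dist_normalizer(dz), pi^2 / 6, tolerance = 1e-5)
})

test_that("shifted exponential density starts at lambda", {
  d <- heavy_dist("exponential", 2, xmin = 1)
  expect_equal(dist_pdf(d, 1), 2)
  expect_equal(dist_ccdf(d, 1), 1)
})

test_that("stretched exponential follows its stated parameterization", {
  lam <- 0.6; bet <- 0.7; xmin <- 2
  d <- heavy_dist("stretched_exponential", c(lam, bet), xmin = xmin)
  x <- c(2, 3.5, 10)
  expect_equal(dist_pdf(d, x),
               bet * lam * x^(bet - 1) * exp(-lam * (x^bet - xmin^bet)),
               tolerance = 1e-12)
})

test_that("evaluation outside the support is an error", {
  d <- heavy_dist("power_law", 2.5, xmin = 2)
  expect_error(dist_pdf(d, 1.999), "below the support")
  dx <- heavy_dist("power_law", 2.5, xmin = 2, xmax = 10)
  expect_error(dist_pdf(dx, 11), "above the support")
  expect_error(dist_pdf(heavy_dist("power_law", 2, xmin = 1,
                                   discrete = TRUE), 1.5), "integer")
})

test_that("cdf and ccdf are consistent, monotone and agree two ways", {
  for (d in example_models()) {
    hi <- if (!is.null(d$xmax)) d$xmax else dist_quantile(d, 0.999)
    x <- seq(d$xmin, hi, length.out = 50)
    cdf <- dist_cdf(d, x)
    ccdf <- dist_ccdf(d, x)
    expect_true(all(diff(cdf) >= -1e-12))
    expect_equal(ccdf, 1 - cdf, tolerance = 1e-9,
                 label = paste("ccdf routes for", d$family))
    expect_equal(dist_ccdf(d, d$xmin), 1, tolerance = 1e-12)
    if (!is.null(d$xmax)) expect_equal(dist_cdf(d, d$xmax), 1,
                                       tolerance = 1e-9)
  }
})

test_that("loglikelihood is the sum of log densities and is additive", {
  d <- heavy_dist("power_law", 2.5, xmin = 1)
  expect_equal(dist_loglik(d, 1), log(1.5))
  a <- c(1.2, 3, 8); b <- c(2, 2, 40)
  expect_equal(dist_loglik(d, c(a, b)),
               dist_loglik(d, a) + dist_loglik(d, b))
  expect_error(dist_loglik(d, numeric(0)), "empty")
  # structural zero mass: brute-force table does not reach the point
  db <- heavy_dist("power_law", 2, xmin = 1, discrete = TRUE,
                   discrete_approximation = 50)
  expect_error(dist_loglik(db, c(2, 60)), "zero probability")
})

test_that("discretization by rounding uses half-integer bins from xmin - 1/2", {
  d <- heavy_dist("exponential", 0.4, xmin = 2)
  m <- discretize(d, "round")
  # mass at an integer is the kernel tail difference over [x-.5, x+.5],
  # renormalized so the lowest edge sits at xmin - 1/2
  lam <- 0.4
  norm <- exp(-lam * 1.5)            # kernel tail at xmin - 0.5, over lambda
  for (x in c(2, 3, 7)) {
    expect_equal(dist_pdf(m, x),
                 (exp(-lam * (x - 0.5)) - exp(-lam * (x + 0.5))) / norm,
                 tolerance = 1e-12)
  }
  # rounding masses decrease wherever the density does
  xs <- 2:60
  expect_true(all(diff(dist_pdf(m, xs)) <= 0))
})

test_that("brute-force discretization normalizes kernel values at integers", {
  d <- heavy_dist("power_law", 2, xmin = 1, xmax = 10)
  m <- discretize(d, 4)
  expect_equal(dist_pdf(m, 1), 1 / (1 + 1/4 + 1/9 + 1/16), tolerance = 1e-12)
  expect_equal(sum(dist_pdf(m, 1:4)), 1, tolerance = 1e-12)
  expect_error(discretize(d, 0.5), "exceed xmin")
})

test_that("constructor validates parameters and support", {
  expect_error(heavy_dist("power_law", 0.9, xmin = 1), "admissible range")
  expect_error(heavy_dist("nope", 1, xmin = 1), "unknown family")
  expect_error(heavy_dist("power_law", 2, xmin = -1), "positive")
  expect_error(heavy_dist("power_law", 2, xmin = 5, xmax = 4), "greater than")
  expect_error(heavy_dist("exponential", -2, xmin = 1), "admissible range")
  # discrete support bounds are snapped to integers
  d <- heavy_dist("power_law", 2, xmin = 1.2, xmax = 9.7, discrete = TRUE)
  expect_identical(c(d$xmin, d$xmax), c(2, 9))
})

test_that("parameters are addressable by name and by position", {
  d <- heavy_dist("lognormal", c(mu = 0.5, sigma = 1.2), xmin = 1)
  expect_equal(parameter_n(d, 1), 0.5)
  expect_equal(parameter_n(d, 2), 1.2)
  expect_identical(parameter_name(d, 1), "mu")
  expect_identical(parameter_name(d, 2), "sigma")
  expect_null(parameter_name(d, 3))
  # named input in any order maps to canonical order
  d2 <- heavy_dist("lognormal", c(sigma = 1.2, mu = 0.5), xmin = 1)
  expect_identical(d$parameters, d2$parameters)
})
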