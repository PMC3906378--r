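# The orchestrated analysis: xmin selection, constraint handling, scan
# records, and session behavior.

test_that("a fixed xmin skips the scan and is echoed", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 300, seed = 1)
  f <- heavy_fit(x, xmin = 2.5, verbose = FALSE)
  expect_true(f$fixed_xmin)
  expect_identical(f$given_xmin, 2.5)
  expect_identical(f$xmin, 2.5)
  expect_null(f$scan)
  expect_false(f$noise_flag)
})

test_that("the scan reproduces an exhaustive per-candidate brute force", {
  x <- dist_rand(heavy_dist("power_law", 2.3, xmin = 2), 200, seed = 42)
  f <- heavy_fit(x, verbose = FALSE)
  # oracle: for every unique value, closed-form exponent + KS distance
  # computed through the standalone functions, then take the minimum
  cands <- sort(unique(x))
  cands <- cands[vapply(cands, function(v) sum(x >= v), numeric(1)) >= 2]
  oracle <- vapply(cands, function(v) {
    tail <- x[x >= v]
    a <- 1 + length(tail) / sum(log(tail / v))
    ks_distance(heavy_dist("power_law", a, xmin = v), tail)
  }, numeric(1))
  expect_identical(f$xmin, cands[which.min(oracle)])
  expect_equal(min(f$scan$Ds), min(oracle), tolerance = 1e-12)
  expect_equal(f$scan$xmins, cands)
  expect_equal(f$scan$Ds, oracle, tolerance = 1e-12)
})

test_that("selected xmin is a scan candidate and its distance is reproducible", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 3), 400, seed = 4)
  f <- heavy_fit(x, verbose = FALSE)
  expect_true(f$xmin %in% f$scan$xmins)
  i <- match(f$xmin, f$scan$xmins)
  pl <- fit_model(f, "power_law")
  expect_equal(f$scan$Ds[i], ks_distance(pl, f$data), tolerance = 1e-12)
  expect_equal(f$scan$alphas[i], unname(pl$parameters[["alpha"]]),
               tolerance = 1e-12)
  # scan arrays are internally coherent
  expect_true(all(f$scan$Ds >= 0))
  expect_true(all(f$scan$sigmas >= 0))
  expect_true(all(f$scan$alphas[f$scan$in_range] > 1))
  expect_identical(nrow(f$scan), length(unique(f$scan$xmins)))
})

test_that("on clean simulated data the recovered xmin never undershoots", {
  for (seed in 1:5) {
    x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 5), 2000, seed = seed)
    f <- heavy_fit(x, verbose = FALSE)
    expect_gte(f$xmin, 5)
  }
})

test_that("restricting the search to a range containing the optimum is a no-op", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 4), 800, seed = 10)
  free <- heavy_fit(x, verbose = FALSE)
  lo <- free$xmin * 0.8; hi <- free$xmin * 1.3
  ranged <- heavy_fit(x, xmin = c(lo, hi), verbose = FALSE)
  expect_identical(ranged$xmin, free$xmin)
  expect_false(ranged$fixed_xmin)
  expect_identical(ranged$given_xmin, c(lo, hi))
  expect_true(all(ranged$scan$xmins >= lo & ranged$scan$xmins <= hi))
})

test_that("rescaling the data rescales xmin and leaves alpha unchanged", {
  x <- dist_rand(heavy_dist("power_law", 2.4, xmin = 2), 600, seed = 13)
  f1 <- heavy_fit(x, verbose = FALSE)
  f2 <- heavy_fit(10 * x, verbose = FALSE)
  expect_equal(f2$xmin, 10 * f1$xmin, tolerance = 1e-9)
  expect_equal(unname(fit_model(f2, "power_law")$parameters[["alpha"]]),
               unname(fit_model(f1, "power_law")$parameters[["alpha"]]),
               tolerance = 1e-6)
})

test_that("an unattainable sigma_threshold falls back with a noise flag", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 500, seed = 3)
  free <- heavy_fit(x, verbose = FALSE)
  expect_warning(f <- heavy_fit(x, sigma_threshold = 1e-6, verbose = FALSE),
                 "No valid fits found.")
  expect_true(f$noise_flag)
  expect_identical(f$xmin, free$xmin)
  expect_false(any(f$scan$in_range))
})

test_that("alpha bounds steer the scan to the constraint boundary", {
  x <- dist_rand(heavy_dist("power_law", 2.0, xmin = 1), 1000, seed = 19)
  f <- heavy_fit(x, parameter_range = list(alpha = c(2.4, NA)),
                 verbose = FALSE)
  expect_false(f$noise_flag)
  expect_gte(unname(fit_model(f, "power_law")$parameters[["alpha"]]),
             2.4 - 1e-9)
})

test_that("predicate parameter ranges mark scan candidates out of range", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 500, seed = 23)
  f <- heavy_fit(x, parameter_range = function(p) p$sigma / p$alpha < 0.05,
                 verbose = FALSE)
  i <- match(f$xmin, f$scan$xmins)
  expect_true(f$scan$in_range[i])
  expect_lt(f$scan$sigmas[i] / f$scan$alphas[i], 0.05)
})

test_that("xmax drops data above it and bends the fitted support", {
  x <- c(dist_rand(heavy_dist("power_law", 2.5, xmin = 2), 500, seed = 2), 1e6)
  f <- heavy_fit(x, xmin = 2, xmax = 1000, verbose = FALSE)
  expect_true(f$fixed_xmax)
  expect_lte(max(f$data), 1000)
  pl <- fit_model(f, "power_law")
  expect_identical(pl$xmax, 1000)
})

test_that("alternative metrics drive the scan and are labelled in it", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 2), 300, seed = 6)
  fv <- heavy_fit(x, xmin_distance = "V", verbose = FALSE)
  expect_true("Vs" %in% names(fv$scan))
  i <- match(fv$xmin, fv$scan$xmins)
  pl <- fit_model(fv, "power_law")
  expect_equal(fv$scan$Vs[i], kuiper_distance(pl, fv$data), tolerance = 1e-12)
  fa <- heavy_fit(x, xmin_distance = "Asquare", verbose = FALSE)
  expect_true("Asquares" %in% names(fa$scan))
})

test_that("session-level fit delegates to the standalone power-law fit", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 3), 400, seed = 9)
  f <- heavy_fit(x, xmin = 3, verbose = FALSE)
  pl <- fit_model(f, "power_law")
  standalone <- fit_power_law(x, xmin = 3)
  expect_equal(unname(pl$parameters[["alpha"]]), standalone$alpha)
  expect_equal(pl$sigma, standalone$sigma)
  expect_equal(pl$D, standalone$D)
  # cached: same object on second access
  expect_identical(fit_model(f, "power_law"), pl)
})

test_that("the scan announces itself and degenerate input errors early", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 50, seed = 1)
  expect_message(heavy_fit(x), "Calculating best minimal value")
  expect_error(heavy_fit(rep(3, 10), verbose = FALSE), "unique values")
  expect_error(heavy_fit(c(-1, 2, 3), verbose = FALSE), "positive")
  expect_error(heavy_fit(c(1.5, 2.5), discrete = TRUE, verbose = FALSE),
               "integer")
})
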