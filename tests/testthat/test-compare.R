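# Loglikelihood-ratio comparisons: hand-checked ratios, the Vuong
# normalization, the nested chi-squared correction, and simulation-based
# sanity of the decisions they produce.

test_that("loglikelihood ratio matches a manual sum on fixed densities", {
  m1 <- heavy_dist("power_law", 2.5, xmin = 1)
  m2 <- heavy_dist("exponential", 1.2, xmin = 1)
  pts <- c(1.3, 2.0, 7.5)
  manual <- sum(log((2.5 - 1) * pts^(-2.5)) -
                log(1.2 * exp(-1.2 * (pts - 1))))
  lr <- loglikelihood_ratio(m1, m2, pts)
  expect_equal(lr$R, manual, tolerance = 1e-12)
  expect_length(lr$diffs, 3)
  # identical models: zero ratio
  expect_equal(loglikelihood_ratio(m1, m1, pts)$R, 0)
})

test_that("swapping candidates negates the ratio and keeps p", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 800, seed = 14)
  f <- heavy_fit(x, xmin = 1, verbose = FALSE)
  ab <- distribution_compare(f, "power_law", "lognormal")
  ba <- distribution_compare(f, "lognormal", "power_law")
  expect_equal(ab$R, -ba$R, tolerance = 1e-9)
  expect_equal(ab$normalized_R, -ba$normalized_R, tolerance = 1e-9)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("the Vuong normalization reproduces the erfc closed form", {
  # build a diff vector whose normalized ratio is exactly 1.431
  target <- 1.431
  n <- 100
  diffs <- c(rep(1, 50), rep(-1, 50)) + target / sqrt(n)
  v <- vuong_p(diffs)
  expect_equal(v$normalized_R, target, tolerance = 1e-9)
  expect_lt(abs(v$p - 0.152), 5e-4)   # printed precision
  # R = 0 gives p = 1; p decreases as |normalized R| grows
  expect_equal(vuong_p(c(-1, 1, -1, 1))$p, 1)
  ps <- vapply(c(0.5, 1, 2, 3), function(t) {
    vuong_p(c(rep(1, 50), rep(-1, 50)) + t / sqrt(n))$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(vuong_p(rep(0.3, 5)), "zero variance")
})

test_that("nested p-values follow the chi-squared form and printed session values", {
  # agreement at the precision of the printed session values (the ratios
  # themselves are printed rounded, so the last digit can wobble one unit)
  expect_lt(abs(nested_p(-0.3818) - 0.3821), 2e-4)
  expect_lt(abs(nested_p(-0.081) - 0.687), 5e-4)
  expect_lt(abs(nested_p(-13.0240) - 3.3303e-07), 1e-10)
  expect_equal(nested_p(0), 1)
  # depends on R only through |R|
  for (r in c(0.2, 1.7, 4)) expect_identical(nested_p(r), nested_p(-r))
  expect_error(nested_p(1, dof_difference = 0), ">= 1")
})

test_that("nestedness is detected from family names and can be overridden", {
  expect_true(detect_nested("power_law", "truncated_power_law"))
  expect_true(detect_nested("stretched_exponential", "exponential"))
  expect_false(detect_nested("power_law", "lognormal"))
  expect_false(detect_nested("power_law", "power_law"))
  expect_error(detect_nested("power_law", "weibull"), "unknown family")
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 500, seed = 2)
  f <- heavy_fit(x, xmin = 1, verbose = FALSE)
  expect_message(distribution_compare(f, "power_law", "truncated_power_law"),
                 "Assuming nested distributions")
  # override: force the Vuong route for a nested pair
  cmp <- distribution_compare(f, "power_law", "truncated_power_law",
                              nested = FALSE)
  expect_false(cmp$nested)
  expect_false(is.na(cmp$normalized_R))
})

test_that("a family compared with itself yields no evidence", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 300, seed = 5)
  f <- heavy_fit(x, xmin = 1, verbose = FALSE)
  cmp <- distribution_compare(f, "lognormal", "lognormal")
  expect_equal(cmp$R, 0)
  expect_equal(cmp$p, 1)
})

test_that("normalized_ratio switches the reported ratio, not the p-value", {
  x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 800, seed = 16)
  f <- heavy_fit(x, xmin = 1, verbose = FALSE)
  raw <- distribution_compare(f, "power_law", "exponential")
  norm <- distribution_compare(f, "power_law", "exponential",
                               normalized_ratio = TRUE)
  expect_equal(raw$p, norm$p)
  expect_equal(raw$ratio, raw$R)
  expect_equal(norm$ratio, norm$normalized_R)
})

test_that("exponential data votes against the power law decisively", {
  wins <- 0L
  for (seed in 1:20) {
    x <- dist_rand(heavy_dist("exponential", 0.25, xmin = 1), 10000,
                   seed = 400 + seed)
    f <- heavy_fit(x, xmin = 1, verbose = FALSE)
    cmp <- distribution_compare(f, "power_law", "exponential")
    if (cmp$R < 0 && cmp$p < 0.05) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("the nested test is close to calibrated under the null", {
  ok <- 0L
  for (seed in 1:50) {
    x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 1000,
                   seed = 700 + seed)
    f <- heavy_fit(x, xmin = 1, verbose = FALSE)
    cmp <- suppressMessages(suppressWarnings(
      distribution_compare(f, "power_law", "truncated_power_law")))
    if (cmp$p >= 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 40L)
})

test_that("the Vuong statistic is roughly standard normal under the null", {
  # two candidates placed symmetrically about the generating lognormal are
  # equally wrong by construction (equal Kullback-Leibler divergence via
  # the log-space symmetry), which is the null of the Vuong test
  gen <- heavy_dist("lognormal", c(1, 0.5), xmin = 0.05)
  m1 <- heavy_dist("lognormal", c(0.8, 0.5), xmin = 0.05)
  m2 <- heavy_dist("lognormal", c(1.2, 0.5), xmin = 0.05)
  zs <- vapply(1:200, function(seed) {
    x <- dist_rand(gen, 300, seed = 900 + seed)
    vuong_p(loglikelihood_ratio(m1, m2, x)$diffs)$normalized_R
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(var(zs), 0.6)
  expect_lt(var(zs), 1.6)
})
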