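# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical machinery: brute-force summation, quadrature,
# dense grids and grid searches.

# Hurwitz zeta by direct summation with an integral tail bound
oracle_zeta <- function(s, q, terms = 2e6) {
  k <- seq(q, q + terms)
  sum(k^(-s)) + (q + terms + 0.5)^(1 - s) / (s - 1)
}

# normalization of a continuous model by adaptive quadrature; integrating
# in log-x keeps slowly decaying power-law tails well conditioned
oracle_integral_pdf <- function(d, upper = NULL) {
  hi <- if (!is.null(d$xmax)) d$xmax else
    if (!is.null(upper)) upper else dist_quantile(d, 1 - 1e-9)
  stats::integrate(function(u) dist_pdf(d, exp(u)) * exp(u),
                   log(d$xmin), log(hi),
                   rel.tol = 1e-9, subdivisions = 1000L)$value
}

# total discrete mass: direct sum over integers plus the analytic tail
oracle_discrete_mass <- function(d, cut = 2e5) {
  hi <- if (!is.null(d$xmax)) d$xmax else cut
  sum(dist_pdf(d, seq(d$xmin, hi)))
}

# KS distance by evaluating |S - P| on a dense grid between data points
oracle_ks_grid <- function(d, x, grid_n = 20000) {
  xs <- sort(x)
  n <- length(xs)
  lo <- d$xmin
  hi <- max(xs)
  g <- seq(lo, hi, length.out = grid_n)
  S <- vapply(g, function(v) mean(xs <= v), numeric(1))
  P <- dist_cdf(d, g)
  # include the exact jump points from both sides
  Sj_hi <- vapply(xs, function(v) mean(xs <= v), numeric(1))
  Sj_lo <- vapply(xs, function(v) mean(xs < v), numeric(1))
  Pj <- dist_cdf(d, xs)
  max(abs(S - P), abs(Sj_hi - Pj), abs(Sj_lo - Pj))
}

# continuous power-law exponent by golden-ratio-free brute force: dense
# grid search on the profile loglikelihood
oracle_alpha_grid <- function(x, xmin, step = 1e-4, lo = 1.01, hi = 6) {
  tail <- x[x >= xmin]
  n <- length(tail)
  sl <- sum(log(tail))
  grid <- seq(lo, hi, by = step)
  ll <- n * log(grid - 1) + n * (grid - 1) * log(xmin) - grid * sl
  grid[which.max(ll)]
}

# discrete power-law exponent by grid search on the zeta likelihood
oracle_alpha_grid_discrete <- function(x, xmin, step = 1e-4,
                                       lo = 1.05, hi = 6) {
  tail <- x[x >= xmin]
  n <- length(tail)
  sl <- sum(log(tail))
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(a) {
    -a * sl - n * log(oracle_zeta(a, xmin, terms = 2e5))
  }, numeric(1))
  grid[which.max(ll)]
}
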