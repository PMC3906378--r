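# Random variate generation and quantile functions for truncated models.
#
# Continuous families use inverse-CDF transforms (closed form wherever the
# kernel tail inverts analytically; numeric bisection for the truncated
# power law's quantile function). Continuous truncated power-law *random*
# generation instead uses rejection sampling from the pure power law with
# acceptance probability exp(-lambda (x - xmin)), which is exact and fast
# for small lambda * xmin. Discrete models invert the exact discrete CDF by
# doubling plus binary search; the discrete power law additionally has a
# fast approximate path x = floor((xmin - 1/2)(1-u)^(-1/(alpha-1)) + 1/2).

#' Quantile function of a truncated model
#'
#' Maps probabilities through the inverse CDF. For discrete models the
#' result is the smallest integer `x` with `cdf(x) >= p` (exact search by
#' doubling and binary search), unless `estimate_discrete` selects the fast
#' approximate transform available for the power law without an `xmax`.
#'
#' @param d a [heavy_dist()] model.
#' @param p probabilities in `[0, 1)`.
#' @param estimate_discrete for discrete power laws: use the fast
#'   approximation instead of the exact search. Defaults to the model's own
#'   `estimate_discrete` setting.
#' @return numeric vector of quantiles; `dist_quantile(d, 0)` is `xmin`.
#' @export
#' @examples
#' d <- heavy_dist("power_law", 2, xmin = 1)
#' dist_quantile(d, 0.75) # 4
dist_quantile <- function(d, p, estimate_discrete = NULL) {
  stopifnot(inherits(d, "heavy_dist"))
  if (any(p < 0 | p >= 1)) stop("`p` must lie in [0, 1)", call. = FALSE)
  if (!d$discrete) return(cont_quantile(d, p))
  est <- if (is.null(estimate_discrete)) d$estimate_discrete else
    isTRUE(estimate_discrete)
  if (est && d$family == "power_law" && is.null(d$xmax) &&
      discrete_flavor(d) == "exact") {
    a <- d$parameters[["alpha"]]
    return(floor((d$xmin - 0.5) * (1 - p)^(-1 / (a - 1)) + 0.5))
  }
  discrete_quantile(d, p)
}

# closed-form / numeric inverse CDF for continuous models
cont_quantile <- function(d, u) {
  p <- d$parameters
  xmin <- d$xmin; xmax <- d$xmax
  out <- switch(d$family,
    power_law = {
      a <- p[["alpha"]]
      if (is.null(xmax)) {
        xmin * (1 - u)^(-1 / (a - 1))
      } else {
        (xmin^(1 - a) - u * (xmin^(1 - a) - xmax^(1 - a)))^(1 / (1 - a))
      }
    },
    exponential = {
      l <- p[["lambda"]]
      span <- if (is.null(xmax)) 1 else -expm1(-l * (xmax - xmin))
      xmin - log1p(-u * span) / l
    },
    stretched_exponential = {
      l <- p[["lambda"]]; b <- p[["beta"]]
      span <- if (is.null(xmax)) 1 else -expm1(-l * (xmax^b - xmin^b))
      (xmin^b - log1p(-u * span) / l)^(1 / b)
    },
    lognormal = {
      plo <- stats::plnorm(xmin, p[["mu"]], p[["sigma"]])
      phi <- if (is.null(xmax)) 1 else
        stats::plnorm(xmax, p[["mu"]], p[["sigma"]])
      stats::qlnorm(plo + u * (phi - plo), p[["mu"]], p[["sigma"]])
    },
    gamma = {
      plo <- stats::pgamma(xmin, p[["k"]], scale = p[["theta"]])
      phi <- if (is.null(xmax)) 1 else
        stats::pgamma(xmax, p[["k"]], scale = p[["theta"]])
      stats::qgamma(plo + u * (phi - plo), p[["k"]], scale = p[["theta"]])
    },
    truncated_power_law = tpl_quantile_numeric(d, u)
  )
  pmax(out, xmin)
}

# bisection inversion of the truncated power-law continuous CDF
tpl_quantile_numeric <- function(d, u) {
  vapply(u, function(ui) {
    if (ui <= 0) return(d$xmin)
    hi <- if (is.null(d$xmax)) {
      h <- d$xmin * 2
      while (dist_cdf_unchecked(d, h) < ui) h <- h * 2
      h
    } else d$xmax
    stats::uniroot(function(x) dist_cdf_unchecked(d, x) - ui,
                   lower = d$xmin, upper = hi, tol = 1e-12)$root
  }, numeric(1L))
}

# cdf evaluation without support validation (internal; x may be any real
# >= xmin for continuous models or integer >= xmin for discrete ones)
dist_cdf_unchecked <- function(d, x) {
  if (!d$discrete) {
    lt_min <- ktail_log(d$family, d$parameters, d$xmin)
    lt_x <- ktail_log(d$family, d$parameters, x)
    lz <- cont_lognorm(d)
    return(pmin(pmax(-expm1(lt_x - lt_min) * exp(lt_min - lz), 0), 1))
  }
  z <- dist_normalizer(d)
  switch(discrete_flavor(d),
    exact = {
      a <- d$parameters[["alpha"]]
      pmin((hurwitz_zeta(a, d$xmin) - hurwitz_zeta(a, x + 1)) / z, 1)
    },
    round = {
      la <- ktail_log(d$family, d$parameters, d$xmin - 0.5)
      lb <- ktail_log(d$family, d$parameters, x + 0.5)
      pmin(exp(ldiffexp(rep_len(la, length(x)), lb)) / z, 1)
    },
    brute = {
      tab <- brute_table(d)
      cm <- cumsum(tab$mass)
      idx <- pmin(pmax(floor(x) - d$xmin + 1, 0), length(cm))
      out <- numeric(length(x))
      out[idx > 0] <- cm[idx[idx > 0]]
      out
    }
  )
}

# exact search: smallest integer x with cdf(x) >= u, vectorized doubling
# followed by binary search on the exact discrete CDF
discrete_quantile <- function(d, u) {
  n <- length(u)
  xmin <- d$xmin
  cap <- if (!is.null(d$xmax)) d$xmax else
    if (discrete_flavor(d) == "brute") max(brute_table(d)$x) else Inf
  lo <- rep(xmin - 1, n)     # invariant: cdf(lo) < u
  hi <- rep(xmin, n)
  step <- rep(1, n)
  repeat {
    need <- dist_cdf_unchecked(d, pmin(hi, cap)) < u & hi < cap
    if (!any(need)) break
    lo[need] <- hi[need]
    hi[need] <- hi[need] + step[need]
    step[need] <- step[need] * 2
  }
  hi <- pmin(hi, cap)
  while (any(hi - lo > 1)) {
    mid <- floor((lo + hi) / 2)
    cm <- dist_cdf_unchecked(d, mid)
    up <- cm >= u & (hi - lo > 1)
    down <- cm < u & (hi - lo > 1)
    hi[up] <- mid[up]
    lo[down] <- mid[down]
  }
  hi
}

#' Generate random variates from a model
#'
#' Draws `n` values by inverse-CDF transform of uniforms, with two special
#' cases: the continuous truncated power law is sampled by rejection from
#' the pure power law with acceptance `exp(-lambda (x - xmin))`, and the
#' discrete power law without an `xmax` has a fast approximate transform
#' selected by `estimate_discrete` (exact search otherwise).
#'
#' @param d a [heavy_dist()] model.
#' @param n number of draws, at least 1.
#' @param seed optional integer; if given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param estimate_discrete override of the model's `estimate_discrete`
#'   setting (discrete power law only).
#' @return numeric vector of length `n` within the model's support.
#' @export
#' @examples
#' d <- heavy_dist("power_law", 2.5, xmin = 5)
#' x <- dist_rand(d, 100, seed = 1)
dist_rand <- function(d, n, seed = NULL, estimate_discrete = NULL) {
  stopifnot(inherits(d, "heavy_dist"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be at least 1", call. = FALSE)
  }
  n <- as.integer(n)
  with_seed(seed, {
    if (!d$discrete && d$family == "truncated_power_law") {
      tpl_rejection(d, n)
    } else {
      dist_quantile(d, stats::runif(n), estimate_discrete = estimate_discrete)
    }
  })
}

# rejection sampler for the continuous exponentially truncated power law
tpl_rejection <- function(d, n) {
  a <- d$parameters[["alpha"]]; l <- d$parameters[["lambda"]]
  xmin <- d$xmin; xmax <- d$xmax
  out <- numeric(0L)
  while (length(out) < n) {
    m <- max(n - length(out), 16L) * 2L
    x <- xmin * (1 - stats::runif(m))^(-1 / (a - 1))
    keep <- stats::runif(m) < exp(-l * (x - xmin))
    if (!is.null(xmax)) keep <- keep & x <= xmax
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}
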