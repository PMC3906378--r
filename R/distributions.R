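# Candidate distribution families over a truncated support [xmin, xmax],
# in continuous and discrete flavors.
#
# Every family is stored as an unnormalized kernel plus its analytic tail
# integral; densities, cumulative functions and likelihoods are derived
# from those in numerically stable (log-scale) forms. Discrete flavors come
# in three kinds:
#   * "exact"  - the analytically known discrete form (power law only,
#                normalized by the Hurwitz zeta function);
#   * "round"  - discretization by rounding: the mass at integer x is the
#                continuous kernel integrated over [x - 1/2, x + 1/2], with
#                the lowest bin edge at xmin - 1/2;
#   * brute force - kernel density evaluated at each integer up to xmax
#                ("xmax" mode) or a user limit (a number N), normalized by
#                the sum.

HV_FAMILIES <- c("power_law", "exponential", "stretched_exponential",
                 "lognormal", "truncated_power_law", "gamma")

HV_PARAM_NAMES <- list(
  power_law             = "alpha",
  exponential           = "lambda",
  stretched_exponential = c("lambda", "beta"),
  lognormal             = c("mu", "sigma"),
  truncated_power_law   = c("alpha", "lambda"),
  gamma                 = c("k", "theta")
)

# Default admissible parameter ranges (lower, upper); NA means unbounded.
HV_DEFAULT_RANGE <- list(
  power_law             = list(alpha = c(1, NA)),
  exponential           = list(lambda = c(0, NA)),
  stretched_exponential = list(lambda = c(0, NA), beta = c(0, NA)),
  lognormal             = list(mu = c(NA, NA), sigma = c(0, NA)),
  truncated_power_law   = list(alpha = c(1, NA), lambda = c(0, NA)),
  gamma                 = list(k = c(0, NA), theta = c(0, NA))
)

#' Supported distribution families
#'
#' @return character vector of the family names understood by
#'   [heavy_dist()], [fit_dist_mle()] and [distribution_compare()].
#' @export
#' @examples
#' supported_distributions()
supported_distributions <- function() HV_FAMILIES

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !(family %in% HV_FAMILIES)) {
    stop("unknown family: ", paste(family, collapse = ", "),
         "; see supported_distributions()", call. = FALSE)
  }
  family
}

# Normalize user parameters to a fully named numeric vector in canonical
# order, accepting positional or named input.
canonical_parameters <- function(family, parameters) {
  nm <- HV_PARAM_NAMES[[family]]
  p <- unlist(parameters, use.names = TRUE)
  if (length(p) != length(nm)) {
    stop(family, " takes ", length(nm), " parameter(s): ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  if (!is.null(names(p)) && all(nzchar(names(p)))) {
    if (!setequal(names(p), nm)) {
      stop("parameter names for ", family, " must be ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
    p <- p[nm]
  } else {
    names(p) <- nm
  }
  p
}

params_in_range <- function(family, parameters, range = NULL) {
  rng <- HV_DEFAULT_RANGE[[family]]
  if (!is.null(range) && !is.function(range)) {
    for (nm in names(range)) {
      if (nm %in% names(rng)) rng[[nm]] <- range[[nm]]
    }
  }
  for (nm in names(rng)) {
    lo <- rng[[nm]][1]; hi <- rng[[nm]][2]
    v <- parameters[[nm]]
    if (!is.finite(v)) return(FALSE)
    if (!is.na(lo) && v < lo) return(FALSE)
    if (!is.na(hi) && v > hi) return(FALSE)
  }
  TRUE
}

#' Construct a distribution model over a truncated support
#'
#' A `heavy_dist` object couples one distribution family with fixed
#' parameter values, a support `[xmin, xmax]` (with `xmax` optional) and a
#' continuous-or-discrete declaration. All probability functions
#' ([dist_pdf()], [dist_cdf()], [dist_ccdf()]), likelihoods
#' ([dist_loglik()]) and random generation ([dist_rand()]) operate on these
#' objects.
#'
#' @param family one of [supported_distributions()].
#' @param parameters numeric vector of parameter values, positional or
#'   named (`power_law`: alpha; `exponential`: lambda;
#'   `stretched_exponential`: lambda, beta; `lognormal`: mu, sigma;
#'   `truncated_power_law`: alpha, lambda; `gamma`: k, theta).
#' @param xmin lower bound of the support, positive.
#' @param xmax optional upper bound, greater than `xmin`.
#' @param discrete if `TRUE` the model is an integer mass function.
#' @param discrete_approximation how a discrete flavor is built: `"exact"`
#'   (power law only; Hurwitz-zeta normalization, the default for that
#'   family), `"round"` (default for all other families), `"xmax"` (brute
#'   force up to `xmax`), or a number giving a fixed brute-force limit.
#' @param estimate_discrete default used by fitting and random generation:
#'   use the fast analytic approximations (`TRUE`) or exact computations.
#' @return an object of class `heavy_dist`.
#' @export
#' @examples
#' d <- heavy_dist("power_law", 2.5, xmin = 1)
#' dist_pdf(d, 1)     # 1.5
#' dist_ccdf(d, 4)    # 0.125
heavy_dist <- function(family, parameters, xmin, xmax = NULL,
                       discrete = FALSE, discrete_approximation = NULL,
                       estimate_discrete = TRUE) {
  family <- check_family(family)
  parameters <- canonical_parameters(family, parameters)
  if (!is.numeric(xmin) || length(xmin) != 1L || !is.finite(xmin) || xmin <= 0) {
    stop("`xmin` must be a single positive number", call. = FALSE)
  }
  if (!is.null(xmax)) {
    if (!is.numeric(xmax) || length(xmax) != 1L || !is.finite(xmax) ||
        xmax <= xmin) {
      stop("`xmax` must be a single number greater than xmin", call. = FALSE)
    }
  }
  if (discrete) {
    xmin <- ceiling(xmin)
    if (!is.null(xmax)) xmax <- floor(xmax)
  }
  if (is.null(discrete_approximation)) {
    discrete_approximation <- if (family == "power_law") "exact" else "round"
  }
  if (is.numeric(discrete_approximation)) {
    if (discrete_approximation <= xmin) {
      stop("fixed brute-force limit must exceed xmin", call. = FALSE)
    }
  } else if (identical(discrete_approximation, "exact")) {
    if (family != "power_law") {
      stop("\"exact\" discrete form is only available for power_law",
           call. = FALSE)
    }
  } else if (identical(discrete_approximation, "xmax")) {
    if (is.null(xmax)) {
      stop("discrete_approximation = \"xmax\" requires an xmax", call. = FALSE)
    }
  } else if (!identical(discrete_approximation, "round")) {
    stop("discrete_approximation must be \"exact\", \"round\", \"xmax\" or a number",
         call. = FALSE)
  }
  # default admissible ranges: alpha > 1, all scale/shape parameters > 0
  strict <- setdiff(names(parameters), "mu")
  lower <- ifelse(strict == "alpha", 1, 0)
  if (any(!is.finite(parameters)) ||
      any(parameters[strict] <= lower)) {
    stop("parameters out of the admissible range for ", family,
         " (alpha > 1; scale and shape parameters > 0)", call. = FALSE)
  }
  d <- structure(
    list(family = family, parameters = parameters, xmin = xmin, xmax = xmax,
         discrete = discrete, discrete_approximation = discrete_approximation,
         estimate_discrete = isTRUE(estimate_discrete), noise_flag = FALSE),
    class = "heavy_dist"
  )
  # validate on the log scale so extreme-but-legitimate parameters (whose
  # normalizer underflows a double) are still accepted
  lz <- if (discrete) log(dist_normalizer(d)) else cont_lognorm(d)
  if (!is.finite(lz)) {
    stop("non-finite normalization constant for ", family,
         " with the given parameters/support", call. = FALSE)
  }
  d
}

#' @export
print.heavy_dist <- function(x, ...) {
  flavor <- if (x$discrete) {
    paste0("discrete (", if (is.numeric(x$discrete_approximation))
      paste0("limit ", x$discrete_approximation) else x$discrete_approximation,
      ")")
  } else "continuous"
  cat(sprintf("<heavy_dist> %s, %s\n", x$family, flavor))
  cat("  parameters:",
      paste(sprintf("%s = %.6g", names(x$parameters), x$parameters),
            collapse = ", "), "\n")
  cat(sprintf("  support: [%g, %s]\n", x$xmin,
              if (is.null(x$xmax)) "Inf" else format(x$xmax)))
  if (isTRUE(x$noise_flag)) cat("  noise_flag: TRUE\n")
  invisible(x)
}

# ---- kernel tails ----------------------------------------------------------
# log of the kernel tail integral T(x) = int_x^Inf kernel(t) dt for each
# family's standard kernel:
#   power_law x^-a | exponential e^(-l x) | stretched b l x^(b-1) e^(-l x^b)
#   lognormal dlnorm | truncated_power_law x^-a e^(-l x) | gamma x^(k-1) e^(-x/th)
ktail_log <- function(family, p, x) {
  switch(family,
    power_law = {
      a <- p[["alpha"]]
      if (a <= 1) stop("power-law kernel tail diverges for alpha <= 1",
                       call. = FALSE)
      (1 - a) * log(x) - log(a - 1)
    },
    exponential = -p[["lambda"]] * x - log(p[["lambda"]]),
    stretched_exponential = -p[["lambda"]] * x^p[["beta"]],
    lognormal = stats::plnorm(x, p[["mu"]], p[["sigma"]],
                              lower.tail = FALSE, log.p = TRUE),
    truncated_power_law = {
      a <- p[["alpha"]]; l <- p[["lambda"]]
      (a - 1) * log(l) + log(uigamma(1 - a, l * x))
    },
    gamma = lgamma(p[["k"]]) + p[["k"]] * log(p[["theta"]]) +
      stats::pgamma(x, p[["k"]], scale = p[["theta"]],
                    lower.tail = FALSE, log.p = TRUE)
  )
}

# log of the kernel density itself
kernel_log <- function(family, p, x) {
  switch(family,
    power_law = -p[["alpha"]] * log(x),
    exponential = -p[["lambda"]] * x,
    stretched_exponential = log(p[["beta"]]) + log(p[["lambda"]]) +
      (p[["beta"]] - 1) * log(x) - p[["lambda"]] * x^p[["beta"]],
    lognormal = stats::dlnorm(x, p[["mu"]], p[["sigma"]], log = TRUE),
    truncated_power_law = -p[["alpha"]] * log(x) - p[["lambda"]] * x,
    gamma = (p[["k"]] - 1) * log(x) - x / p[["theta"]]
  )
}

# log(exp(la) - exp(lb)) computed stably for la >= lb (lb may be -Inf)
ldiffexp <- function(la, lb) {
  out <- la + log1p(-exp(lb - la))
  out[is.infinite(lb) & lb < 0] <- la[is.infinite(lb) & lb < 0]
  out
}

# log of the continuous normalizer over [xmin, xmax]
cont_lognorm <- function(d) {
  la <- ktail_log(d$family, d$parameters, d$xmin)
  lb <- if (is.null(d$xmax)) -Inf else ktail_log(d$family, d$parameters, d$xmax)
  ldiffexp(la, lb)
}

# brute-force mass table for discrete models; returns list(x, mass)
brute_table <- function(d) {
  limit <- if (is.numeric(d$discrete_approximation)) {
    floor(d$discrete_approximation)
  } else {
    d$xmax
  }
  xs <- seq.int(d$xmin, limit)
  lk <- kernel_log(d$family, d$parameters, xs)
  w <- exp(lk - max(lk))
  list(x = xs, mass = w / sum(w), lognorm = log(sum(w)) + max(lk))
}

discrete_flavor <- function(d) {
  if (is.numeric(d$discrete_approximation)) "brute" else
    switch(d$discrete_approximation, exact = "exact", round = "round",
           xmax = "brute")
}

#' Normalization constant of a model's kernel
#'
#' Returns the constant \eqn{Z} such that the family's standard kernel
#' divided by \eqn{Z} integrates (continuous) or sums (discrete) to one
#' over the support. For the discrete rounding flavor the "kernel" of an
#' integer is its half-open bin integral \eqn{T(x-1/2) - T(x+1/2)}, which
#' makes \eqn{Z = T(x_{min}-1/2) - T(x_{max}+1/2)}.
#'
#' @param d a [heavy_dist()] model.
#' @return a positive number.
#' @export
#' @examples
#' dist_normalizer(heavy_dist("power_law", 2.5, xmin = 1)) # 1/(alpha-1)
dist_normalizer <- function(d) {
  stopifnot(inherits(d, "heavy_dist"))
  if (!d$discrete) return(exp(cont_lognorm(d)))
  switch(discrete_flavor(d),
    exact = {
      a <- d$parameters[["alpha"]]
      if (a <= 1 && is.null(d$xmax)) {
        stop("discrete power law with alpha <= 1 needs an xmax", call. = FALSE)
      }
      hurwitz_zeta(a, d$xmin) -
        if (is.null(d$xmax)) 0 else hurwitz_zeta(a, d$xmax + 1)
    },
    round = {
      la <- ktail_log(d$family, d$parameters, d$xmin - 0.5)
      lb <- if (is.null(d$xmax)) -Inf else
        ktail_log(d$family, d$parameters, d$xmax + 0.5)
      exp(ldiffexp(la, lb))
    },
    brute = exp(brute_table(d)$lognorm)
  )
}

check_support <- function(d, x, what = "x") {
  if (length(x) == 0L) stop("empty ", what, call. = FALSE)
  if (any(x < d$xmin)) {
    stop(what, " below the support lower bound xmin = ", d$xmin, call. = FALSE)
  }
  if (!is.null(d$xmax) && any(x > d$xmax)) {
    stop(what, " above the support upper bound xmax = ", d$xmax, call. = FALSE)
  }
  if (d$discrete && !is_whole(x)) {
    stop(what, " must be integer-valued for a discrete model", call. = FALSE)
  }
  invisible(x)
}

#' Probability density / mass function of a fitted or theoretical model
#'
#' @param d a [heavy_dist()] model.
#' @param x numeric vector of evaluation points; must lie within the
#'   model's support (integers for a discrete model).
#' @return density values (continuous) or probability masses (discrete).
#' @export
#' @examples
#' dist_pdf(heavy_dist("power_law", 2.5, xmin = 1), c(1, 2, 4))
dist_pdf <- function(d, x) {
  stopifnot(inherits(d, "heavy_dist"))
  check_support(d, x)
  if (!d$discrete) {
    return(exp(kernel_log(d$family, d$parameters, x) - cont_lognorm(d)))
  }
  switch(discrete_flavor(d),
    exact = x^(-d$parameters[["alpha"]]) / dist_normalizer(d),
    round = {
      la <- ktail_log(d$family, d$parameters, x - 0.5)
      lb <- ktail_log(d$family, d$parameters, x + 0.5)
      exp(ldiffexp(la, lb)) / dist_normalizer(d)
    },
    brute = {
      tab <- brute_table(d)
      m <- numeric(length(x))
      idx <- match(round(x), tab$x)
      m[!is.na(idx)] <- tab$mass[idx[!is.na(idx)]]
      m
    }
  )
}

#' Cumulative distribution function \eqn{P(X \le x)}
#'
#' The same convention, \eqn{P(X \le x)}, is used for continuous and
#' discrete models; for discrete models the argument is floored first.
#'
#' @inheritParams dist_pdf
#' @return probabilities, nondecreasing in `x`.
#' @export
dist_cdf <- function(d, x) {
  stopifnot(inherits(d, "heavy_dist"))
  if (length(x) == 0L) stop("empty x", call. = FALSE)
  if (any(x < d$xmin)) {
    stop("x below the support lower bound xmin = ", d$xmin, call. = FALSE)
  }
  if (!is.null(d$xmax) && any(x > d$xmax)) {
    stop("x above the support upper bound xmax = ", d$xmax, call. = FALSE)
  }
  if (!d$discrete) {
    lt_min <- ktail_log(d$family, d$parameters, d$xmin)
    lt_x <- ktail_log(d$family, d$parameters, x)
    lz <- cont_lognorm(d)
    p <- -expm1(lt_x - lt_min) * exp(lt_min - lz)
    return(pmin(pmax(p, 0), 1))
  }
  xf <- floor(x + 1e-9)
  z <- dist_normalizer(d)
  switch(discrete_flavor(d),
    exact = {
      a <- d$parameters[["alpha"]]
      pmin(pmax((hurwitz_zeta(a, d$xmin) - hurwitz_zeta(a, xf + 1)) / z, 0), 1)
    },
    round = {
      la <- ktail_log(d$family, d$parameters, d$xmin - 0.5)
      lb <- ktail_log(d$family, d$parameters, xf + 0.5)
      pmin(pmax(exp(ldiffexp(la, lb)) / z, 0), 1)
    },
    brute = {
      tab <- brute_table(d)
      cm <- cumsum(tab$mass)
      idx <- pmin(pmax(xf - d$xmin + 1, 0), length(cm))
      out <- numeric(length(x))
      out[idx > 0] <- cm[idx[idx > 0]]
      out
    }
  )
}

#' Complementary cumulative distribution (survival) function
#'
#' Defined as \eqn{1 - P(X \le x)} but computed directly from the kernel
#' tail for numerical accuracy deep in the tail.
#'
#' @inheritParams dist_pdf
#' @return tail probabilities, nonincreasing in `x`.
#' @export
#' @examples
#' dist_ccdf(heavy_dist("power_law", 2.5, xmin = 1), 4) # 0.125
dist_ccdf <- function(d, x) {
  stopifnot(inherits(d, "heavy_dist"))
  if (length(x) == 0L) stop("empty x", call. = FALSE)
  if (any(x < d$xmin)) {
    stop("x below the support lower bound xmin = ", d$xmin, call. = FALSE)
  }
  if (!is.null(d$xmax) && any(x > d$xmax)) {
    stop("x above the support upper bound xmax = ", d$xmax, call. = FALSE)
  }
  if (!d$discrete) {
    lt_x <- ktail_log(d$family, d$parameters, x)
    lt_max <- if (is.null(d$xmax)) -Inf else
      ktail_log(d$family, d$parameters, d$xmax)
    lz <- cont_lognorm(d)
    return(pmin(pmax(exp(ldiffexp(lt_x, rep(lt_max, length(x))) - lz), 0), 1))
  }
  pmin(pmax(1 - dist_cdf(d, x), 0), 1)
}

# log density/mass, computed without leaving the log scale so that deep
# tail points never underflow to a spurious zero
dist_logpdf <- function(d, x) {
  check_support(d, x)
  if (!d$discrete) {
    return(kernel_log(d$family, d$parameters, x) - cont_lognorm(d))
  }
  switch(discrete_flavor(d),
    exact = -d$parameters[["alpha"]] * log(x) - log(dist_normalizer(d)),
    round = {
      la <- ktail_log(d$family, d$parameters, x - 0.5)
      lb <- ktail_log(d$family, d$parameters, x + 0.5)
      ldiffexp(la, lb) - log(dist_normalizer(d))
    },
    brute = log(dist_pdf(d, x))
  )
}

#' Loglikelihood of data under a model
#'
#' Sum of log density (continuous) or log mass (discrete) over the data
#' points, evaluated on the log scale throughout. Points with zero
#' probability under the model raise an error.
#'
#' @inheritParams dist_pdf
#' @param x data vector within the model's support.
#' @return a single number.
#' @export
dist_loglik <- function(d, x) {
  stopifnot(inherits(d, "heavy_dist"))
  if (length(x) == 0L) stop("empty data", call. = FALSE)
  lp <- dist_logpdf(d, x)
  if (any(!is.finite(lp))) {
    stop("data point with zero probability under the ", d$family, " model",
         call. = FALSE)
  }
  sum(lp)
}

#' Discretize a continuous model into an integer mass function
#'
#' @param d a continuous [heavy_dist()] model.
#' @param discrete_approximation `"round"` for discretization by rounding
#'   (half-integer bin sums), `"xmax"` for brute force up to the model's
#'   `xmax`, or a number giving a fixed brute-force limit.
#' @return a discrete `heavy_dist` over the integers of the support.
#' @export
#' @examples
#' d <- heavy_dist("power_law", 2, xmin = 1, xmax = 10)
#' m <- discretize(d, 4)
#' dist_pdf(m, 1) # 1 / (1 + 1/4 + 1/9 + 1/16)
discretize <- function(d, discrete_approximation = "round") {
  stopifnot(inherits(d, "heavy_dist"))
  if (d$discrete) stop("model is already discrete", call. = FALSE)
  heavy_dist(d$family, d$parameters, xmin = d$xmin, xmax = d$xmax,
             discrete = TRUE, discrete_approximation = discrete_approximation,
             estimate_discrete = d$estimate_discrete)
}
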