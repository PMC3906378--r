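# Maximum likelihood fitting of the power law on a fixed scaling range.
#
# The continuous case without an upper bound has the classic closed form
#   alpha = 1 + n / sum(log(x_i / xmin)),   sigma = (alpha - 1) / sqrt(n).
# The discrete case has an analytic approximation that replaces xmin with
# xmin - 1/2 (accurate to about 1% for xmin >= 6), or an exact fit by
# numerical maximization of the Hurwitz-zeta likelihood. Fits with an xmax
# are always numerical. sigma reuses the continuous closed form throughout,
# as a documented approximation.

# widest alpha considered by the numerical fits; likelihoods are strictly
# concave in alpha so the interior optimum is found whenever it exists
ALPHA_MAX <- 60

#' Fit a power law to the tail of a sample
#'
#' Estimates the exponent `alpha` of a power law on the data within
#' `[xmin, xmax]`, by the analytic maximum-likelihood formulas when they
#' exist and by numerical likelihood maximization otherwise.
#'
#' @param x numeric sample (only values within the range are used).
#' @param xmin lower bound of the scaling range.
#' @param xmax optional upper bound; data above it is ignored.
#' @param discrete fit the discrete (integer) form.
#' @param estimate_discrete for discrete data without an `xmax`, use the
#'   fast analytic estimate (default) instead of the exact numerical fit;
#'   with an `xmax` the exact fit is used and a warning is given.
#' @param alpha_range optional `c(lower, upper)` constraint on `alpha`; the
#'   likelihood is concave in `alpha`, so a violated bound yields the
#'   boundary value.
#' @param compute_distance also compute the Kolmogorov-Smirnov distance `D`
#'   between the tail data and the fit.
#' @return an object of class `power_law_fit`: a list with `alpha`, `sigma`
#'   (standard error `(alpha-1)/sqrt(n_tail)`), `D`, `n_tail`, `xmin`,
#'   `xmax`, `discrete`, and `method` (`"analytic"`, `"estimate"` or
#'   `"numeric"`).
#' @export
#' @examples
#' fit_power_law(c(1, 2, 4, 8), xmin = 1) # alpha = 1 + 4/(6 log 2)
fit_power_law <- function(x, xmin, xmax = NULL, discrete = FALSE,
                          estimate_discrete = TRUE,
                          alpha_range = NULL, compute_distance = TRUE) {
  check_positive_values(x)
  tail <- x[x >= xmin & (if (is.null(xmax)) TRUE else x <= xmax)]
  n <- length(tail)
  if (n < 2L) {
    stop("need at least 2 data points in [xmin, xmax]", call. = FALSE)
  }
  if (discrete && !is_whole(tail)) {
    stop("discrete fit requires integer data", call. = FALSE)
  }
  if (all(tail == xmin)) {
    stop_degenerate("degenerate data: all points equal xmin")
  }
  lo <- 1 + 1e-8; hi <- ALPHA_MAX
  if (!is.null(alpha_range)) {
    if (!is.na(alpha_range[1])) lo <- max(lo, alpha_range[1])
    if (!is.na(alpha_range[2])) hi <- min(hi, alpha_range[2])
    if (lo > hi) stop("empty alpha range", call. = FALSE)
  }
  sum_log <- sum(log(tail))
  method <- "numeric"
  if (!discrete && is.null(xmax)) {
    alpha <- 1 + n / (sum_log - n * log(xmin))
    method <- "analytic"
  } else if (discrete && estimate_discrete) {
    if (!is.null(xmax)) {
      warning("the analytic discrete estimate is only valid without an xmax; ",
              "using the exact numerical fit", call. = FALSE)
      alpha <- optimize_alpha_discrete(sum_log, n, xmin, xmax, lo, hi)
    } else {
      alpha <- 1 + n / (sum_log - n * log(xmin - 0.5))
      method <- "estimate"
    }
  } else if (discrete) {
    alpha <- optimize_alpha_discrete(sum_log, n, xmin, xmax, lo, hi)
  } else {
    # continuous with xmax: maximize n log((a-1)/(xmin^(1-a)-xmax^(1-a))) - a sum_log
    nll <- function(a) {
      -(n * (log(a - 1) - log(xmin^(1 - a) - xmax^(1 - a))) - a * sum_log)
    }
    alpha <- stats::optimize(nll, c(lo, hi), tol = 1e-10)$minimum
  }
  alpha <- min(max(alpha, lo), hi)
  sigma <- (alpha - 1) / sqrt(n)
  D <- NA_real_
  if (compute_distance) {
    model <- heavy_dist("power_law", alpha, xmin = xmin, xmax = xmax,
                        discrete = discrete,
                        estimate_discrete = estimate_discrete)
    D <- ks_distance(model, tail)
  }
  structure(
    list(alpha = alpha, sigma = sigma, D = D, n_tail = n, xmin = xmin,
         xmax = xmax, discrete = discrete, method = method),
    class = "power_law_fit"
  )
}

optimize_alpha_discrete <- function(sum_log, n, xmin, xmax, lo, hi) {
  nll <- function(a) {
    z <- hurwitz_zeta(a, xmin) -
      if (is.null(xmax)) 0 else hurwitz_zeta(a, xmax + 1)
    a * sum_log + n * log(z)
  }
  stats::optimize(nll, c(lo, hi), tol = 1e-10)$minimum
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s, %s): alpha = %.4f, sigma = %.4f, D = %.4f\n",
              if (x$discrete) "discrete" else "continuous", x$method,
              x$alpha, x$sigma, x$D))
  cat(sprintf("  n_tail = %d, xmin = %g, xmax = %s\n", x$n_tail, x$xmin,
              if (is.null(x$xmax)) "Inf" else format(x$xmax)))
  invisible(x)
}
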