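# Distance metrics between an empirical sample and a fitted model, used
# both for selecting the scaling range and for minimum-distance fitting.
#
# All three metrics evaluate the empirical step function two-sidedly (just
# before and at each jump), so the supremum over the whole line is found
# exactly for the Kolmogorov-Smirnov and Kuiper statistics.

#' Empirical cumulative distribution function
#'
#' @param values nonempty numeric vector.
#' @return a list with `x` (sorted unique values) and `p` (the cumulative
#'   probabilities `P(X <= x)`, merging ties).
#' @export
#' @examples
#' empirical_cdf(c(1, 2, 2, 3))
empirical_cdf <- function(values) {
  if (length(values) == 0L) stop("empty data", call. = FALSE)
  x <- sort(unique(values))
  counts <- tabulate(match(values, x), nbins = length(x))
  list(x = x, p = cumsum(counts) / length(values))
}

# Evaluate the empirical and model CDFs so that the supremum of |S - P|
# over the whole support is attained on the returned grid. For continuous
# models the empirical step is compared two-sidedly against P at each data
# point. A discrete model's CDF jumps at the same integers as the data, so
# the left-side comparison instead pairs the empirical value below a data
# point with the model CDF at the preceding integer (which also covers
# unobserved integers inside gaps).
metric_steps <- function(model, tail_data) {
  e <- empirical_cdf(tail_data)
  P <- dist_cdf(model, e$x)
  if (model$discrete) {
    prev_ok <- e$x - 1 >= model$xmin
    P_lo <- numeric(length(e$x))
    P_lo[prev_ok] <- dist_cdf(model, e$x[prev_ok] - 1)
  } else {
    P_lo <- P
  }
  list(x = e$x, P = P, P_lo = P_lo,
       S_hi = e$p, S_lo = c(0, e$p[-length(e$p)]),
       w = tabulate(match(tail_data, e$x), nbins = length(e$x)))
}

#' Kolmogorov-Smirnov distance between data and a model
#'
#' \eqn{D = \sup_x |S(x) - P(x)|} where `S` is the empirical CDF of the
#' tail data and `P` the model CDF, evaluated at each data point from both
#' sides of the empirical step.
#'
#' @param model a [heavy_dist()] whose support contains the data.
#' @param tail_data nonempty data within the model support.
#' @return a number in `[0, 1]`.
#' @export
ks_distance <- function(model, tail_data) {
  m <- metric_steps(model, tail_data)
  max(pmax(abs(m$S_hi - m$P), abs(m$S_lo - m$P_lo)))
}

#' Kuiper distance between data and a model
#'
#' \eqn{V = \sup_x (S(x) - P(x)) + \sup_x (P(x) - S(x))}, which weights
#' both tails of the distribution; always at least as large as the
#' Kolmogorov-Smirnov distance.
#'
#' @inheritParams ks_distance
#' @return a number in `[0, 2]`.
#' @export
kuiper_distance <- function(model, tail_data) {
  m <- metric_steps(model, tail_data)
  max(0, m$S_hi - m$P, m$S_lo - m$P_lo) +
    max(0, m$P - m$S_hi, m$P_lo - m$S_lo)
}

#' Anderson-Darling distance between data and a model
#'
#' The tail-weighted statistic
#' \eqn{A^2 = \sum_i (S(x_i) - P(x_i))^2 / (P(x_i)(1 - P(x_i)))}, summed
#' over the data points (ties weighted by multiplicity) with terms where
#' `P` is 0 or 1 dropped. This summation form, rather than the classic
#' rank-based formula, keeps the statistic defined for arbitrary fitted
#' models; it is a deliberate implementation choice.
#'
#' @inheritParams ks_distance
#' @return a nonnegative number.
#' @export
anderson_darling_distance <- function(model, tail_data) {
  m <- metric_steps(model, tail_data)
  keep <- m$P > 0 & m$P < 1
  sum(m$w[keep] * (m$S_hi[keep] - m$P[keep])^2 /
        (m$P[keep] * (1 - m$P[keep])))
}

xmin_distance_fun <- function(metric) {
  switch(metric,
    D = ks_distance,
    V = kuiper_distance,
    Asquare = anderson_darling_distance,
    stop("unknown xmin_distance: ", metric, call. = FALSE)
  )
}

#' Keep the data inside the fitted scaling range
#'
#' @param values numeric data vector.
#' @param xmin,xmax range bounds (xmax optional).
#' @param original_data if `TRUE`, return everything unfiltered.
#' @return the values in `[xmin, xmax]` (both bounds inclusive).
#' @export
#' @examples
#' tail_filter(c(1, 5, 50), xmin = 5)
tail_filter <- function(values, xmin, xmax = NULL, original_data = FALSE) {
  if (original_data) return(values)
  values[values >= xmin & (if (is.null(xmax)) TRUE else values <= xmax)]
}
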