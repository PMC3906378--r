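# Model-free empirical summaries and thin base-graphics plot wrappers.
#
# Heavy-tailed samples are best shown on log-log axes, where linearly
# spaced histogram bins starve the tail of counts; the default here is
# logarithmic binning (exponentially widening bins, anchored at powers of
# ten) with counts turned into a density by dividing by n times the bin
# width. CDF/CCDF point sets need no binning; the CCDF uses the
# P(X >= x) convention so the largest observation stays visible on
# logarithmic axes.

#' Binned probability density of a sample
#'
#' @param values positive numeric sample.
#' @param linear_bins use equal-width bins instead of logarithmic ones.
#' @param n_bins optional explicit number of bins spanning
#'   `[min(values), max(values)]` (geometric in log mode, equal-width in
#'   linear mode); overrides `bins_per_decade`.
#' @param bins_per_decade density of the default logarithmic grid, which
#'   is anchored at powers of 10 and rounded outward so every observation
#'   falls inside a bin.
#' @return a list of class `binned_pdf` with `bin_edges` (length m+1) and
#'   `probabilities` (length m, density-normalized:
#'   `sum(probabilities * diff(bin_edges)) == 1`).
#' @export
#' @examples
#' p <- pdf_points(c(1, 10, 100, 1000), bins_per_decade = 1)
#' p$probabilities # 0.25 / bin width in each decade
pdf_points <- function(values, linear_bins = FALSE, n_bins = NULL,
                       bins_per_decade = 10) {
  check_positive_values(values)
  n <- length(values)
  if (linear_bins) {
    m <- if (is.null(n_bins)) max(1L, ceiling(sqrt(n))) else as.integer(n_bins)
    edges <- seq(min(values), max(values), length.out = m + 1L)
    if (edges[1] == edges[m + 1L]) edges <- c(edges[1], edges[1] * (1 + 1e-9))
  } else if (!is.null(n_bins)) {
    edges <- exp(seq(log(min(values)), log(max(values)),
                     length.out = as.integer(n_bins) + 1L))
  } else {
    e_lo <- floor(log10(min(values)) * bins_per_decade) / bins_per_decade
    e_hi <- ceiling(log10(max(values)) * bins_per_decade) / bins_per_decade
    if (10^e_hi <= max(values)) e_hi <- e_hi + 1 / bins_per_decade
    edges <- 10^seq(e_lo, e_hi, by = 1 / bins_per_decade)
  }
  # left-closed bins, last bin closed on both sides
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  widths <- diff(edges)
  structure(list(bin_edges = edges, probabilities = counts / (n * widths)),
            class = "binned_pdf")
}

#' Empirical CDF and CCDF point sets
#'
#' `cdf_points()` returns `P(X <= x)` and `ccdf_points()` returns
#' `P(X >= x)` at the sorted unique observed values. Under these
#' conventions `ccdf` is 1 at the smallest value and strictly positive
#' everywhere, and `cdf(x) + ccdf(x) = 1 + P(X = x)` at every observed
#' point.
#'
#' @param values nonempty numeric sample.
#' @return a list with `x` (sorted unique values) and `p` (probabilities).
#' @export
#' @examples
#' ccdf_points(c(1, 2, 3))$p # 1, 2/3, 1/3
cdf_points <- function(values) {
  empirical_cdf(values)
}

#' @rdname cdf_points
#' @export
ccdf_points <- function(values) {
  e <- empirical_cdf(values)
  list(x = e$x, p = 1 - c(0, e$p[-length(e$p)]))
}

# shared scaffolding for the plot wrappers: resolve the plotted (x, y)
# point set for raw data / sessions / models, then draw
plot_xy <- function(x, y, add, log = "xy", xlab, ylab, type, ...) {
  keep <- y > 0 & x > 0
  if (add) {
    graphics::lines(x[keep], y[keep], type = type, ...)
  } else {
    graphics::plot(x[keep], y[keep], log = log, xlab = xlab, ylab = ylab,
                   type = type, ...)
  }
  invisible(list(x = x[keep], y = y[keep]))
}

model_grid <- function(d, data = NULL) {
  lo <- if (is.null(data)) d$xmin else max(min(data), d$xmin)
  hi <- if (!is.null(data)) max(data) else
    if (!is.null(d$xmax)) d$xmax else dist_quantile(d, 1 - 1e-4)
  if (d$discrete) {
    xs <- unique(round(exp(seq(log(lo), log(hi), length.out = 200))))
  } else {
    xs <- exp(seq(log(lo), log(hi), length.out = 200))
  }
  xs[xs >= d$xmin & (if (is.null(d$xmax)) TRUE else xs <= d$xmax)]
}

#' Plot empirical or fitted probability functions on log-log axes
#'
#' `plot_pdf`, `plot_cdf` and `plot_ccdf` are generics with methods for
#' raw numeric data, fitted sessions ([heavy_fit()]; plots the tail used
#' for fitting unless `original_data = TRUE`) and theoretical models
#' ([heavy_dist()]; drawn as a curve on a geometric grid over the fitted
#' support, restrictable by passing `data`). Additional arguments are
#' passed through to the base graphics calls; `add = TRUE` draws into the
#' current plot. Empty bins are dropped from the display (zero has no
#' logarithm) but retained in [pdf_points()] output.
#'
#' @param x data vector, `heavy_fit` session, or `heavy_dist` model.
#' @param ... passed to [graphics::plot()] / [graphics::lines()], plus
#'   method-specific options: `linear_bins`, `n_bins`, `bins_per_decade`
#'   (data pdf), `original_data` (sessions), `data` (models).
#' @param add add to the current plot instead of opening a new one.
#' @return invisibly, the plotted point set.
#' @export
plot_pdf <- function(x, ..., add = FALSE) UseMethod("plot_pdf")

#' @export
plot_pdf.numeric <- function(x, ..., add = FALSE, linear_bins = FALSE,
                             n_bins = NULL, bins_per_decade = 10) {
  b <- pdf_points(x, linear_bins = linear_bins, n_bins = n_bins,
                  bins_per_decade = bins_per_decade)
  centers <- sqrt(b$bin_edges[-1] * b$bin_edges[-length(b$bin_edges)])
  plot_xy(centers, b$probabilities, add, xlab = "x", ylab = "p(x)",
          type = "l", ...)
}

#' @export
plot_pdf.heavy_fit <- function(x, ..., add = FALSE, original_data = FALSE) {
  v <- if (original_data) x$values else x$data
  plot_pdf.numeric(v, ..., add = add)
}

#' @export
plot_pdf.heavy_dist <- function(x, ..., add = FALSE, data = NULL) {
  xs <- model_grid(x, data)
  plot_xy(xs, dist_pdf(x, xs), add, xlab = "x", ylab = "p(x)",
          type = "l", ...)
}

#' @rdname plot_pdf
#' @export
plot_cdf <- function(x, ..., add = FALSE) UseMethod("plot_cdf")

#' @export
plot_cdf.numeric <- function(x, ..., add = FALSE) {
  e <- cdf_points(x)
  plot_xy(e$x, e$p, add, xlab = "x", ylab = "P(X <= x)", type = "s", ...)
}

#' @export
plot_cdf.heavy_fit <- function(x, ..., add = FALSE, original_data = FALSE) {
  v <- if (original_data) x$values else x$data
  plot_cdf.numeric(v, ..., add = add)
}

#' @export
plot_cdf.heavy_dist <- function(x, ..., add = FALSE, data = NULL) {
  xs <- model_grid(x, data)
  plot_xy(xs, dist_cdf(x, xs), add, xlab = "x", ylab = "P(X <= x)",
          type = "l", ...)
}

#' @rdname plot_pdf
#' @export
plot_ccdf <- function(x, ..., add = FALSE) UseMethod("plot_ccdf")

#' @export
plot_ccdf.numeric <- function(x, ..., add = FALSE) {
  e <- ccdf_points(x)
  plot_xy(e$x, e$p, add, xlab = "x", ylab = "P(X >= x)", type = "s", ...)
}

#' @export
plot_ccdf.heavy_fit <- function(x, ..., add = FALSE, original_data = FALSE) {
  v <- if (original_data) x$values else x$data
  plot_ccdf.numeric(v, ..., add = add)
}

#' @export
plot_ccdf.heavy_dist <- function(x, ..., add = FALSE, data = NULL) {
  xs <- model_grid(x, data)
  plot_xy(xs, dist_ccdf(x, xs), add, xlab = "x", ylab = "P(X >= x)",
          type = "l", ...)
}
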