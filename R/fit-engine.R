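# Orchestration of a full analysis: scaling-range selection, power-law
# fitting, and lazily fitted candidate models for comparison.
#
# The optimal xmin is found by fitting a power law starting from each
# unique value in the dataset and selecting the candidate minimizing the
# chosen distance metric (Kolmogorov-Smirnov by default). Candidate fits
# violating a sigma_threshold or parameter_range constraint are discarded;
# if no candidate survives, the constraints are dropped, the global
# minimum is selected, and the session's noise_flag is raised.

#' Fit heavy-tailed distributions to a sample
#'
#' The main entry point of the package: wraps a dataset, selects (or
#' accepts) the scaling range, fits the power law, and exposes all other
#' candidate families through [fit_model()] and [distribution_compare()].
#'
#' @param values positive numeric sample (positive integers when
#'   `discrete = TRUE`).
#' @param discrete treat the data as integer-valued and fit discrete
#'   flavors of every family.
#' @param xmin `NULL` to search every unique data value (the default), a
#'   single number to fix the lower bound, or `c(lo, hi)` to restrict the
#'   search to that range (inclusive).
#' @param xmax optional upper bound of the scaling range; data above it is
#'   ignored for fitting.
#' @param estimate_discrete use the fast analytic discrete power-law
#'   estimate during scanning and fitting (default), or the exact
#'   Hurwitz-zeta fit.
#' @param discrete_approximation discrete flavor for non-power-law
#'   families; see [heavy_dist()].
#' @param sigma_threshold discard candidate `xmin` values whose fitted
#'   standard error `sigma` exceeds this.
#' @param parameter_range named list of `c(lower, upper)` bounds on fitted
#'   parameters (for the power law: `alpha`, `sigma`), or a predicate
#'   `function(pars)` evaluated on each candidate fit.
#' @param fit_method `"ML"` (maximum likelihood, default) or `"KS"`
#'   (minimum Kolmogorov-Smirnov distance estimation).
#' @param xmin_distance distance metric minimized over candidate `xmin`
#'   values: `"D"` (Kolmogorov-Smirnov, default), `"V"` (Kuiper) or
#'   `"Asquare"` (Anderson-Darling).
#' @param verbose emit the scan progress message.
#' @return an object of class `heavy_fit` with elements `xmin`, `xmax`,
#'   `scan` (the per-candidate record, `NULL` when `xmin` was fixed),
#'   `noise_flag`, `data` (the tail used for fitting), `values` (the
#'   original sample), echo fields `fixed_xmin`, `given_xmin`,
#'   `fixed_xmax`, and a cache of fitted models.
#' @export
#' @examples
#' x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 500, seed = 1)
#' fit <- heavy_fit(x, verbose = FALSE)
#' fit$xmin
#' fit_model(fit, "power_law")$parameters
heavy_fit <- function(values, discrete = FALSE, xmin = NULL, xmax = NULL,
                      estimate_discrete = TRUE,
                      discrete_approximation = NULL,
                      sigma_threshold = NULL, parameter_range = NULL,
                      fit_method = c("ML", "KS"),
                      xmin_distance = c("D", "V", "Asquare"),
                      verbose = TRUE) {
  fit_method <- match.arg(fit_method)
  xmin_distance <- match.arg(xmin_distance)
  check_positive_values(values)
  if (discrete && !is_whole(values)) {
    stop("`discrete = TRUE` requires integer-valued data", call. = FALSE)
  }
  if (!is.null(sigma_threshold) && sigma_threshold <= 0) {
    stop("`sigma_threshold` must be positive", call. = FALSE)
  }
  given_xmin <- xmin
  fixed_xmin <- !is.null(xmin) && length(xmin) == 1L
  if (!is.null(xmin) && length(xmin) == 2L && xmin[1] >= xmin[2]) {
    stop("xmin range must satisfy lo < hi", call. = FALSE)
  }
  fixed_xmax <- !is.null(xmax)

  noise_flag <- FALSE
  scan <- NULL
  if (fixed_xmin) {
    sel_xmin <- if (discrete) ceiling(xmin) else xmin
  } else {
    if (verbose) message("Calculating best minimal value for power law fit")
    sc <- scan_xmins(values, discrete = discrete, xmax = xmax,
                     estimate_discrete = estimate_discrete,
                     xmin_range = if (is.null(xmin)) NULL else xmin,
                     sigma_threshold = sigma_threshold,
                     parameter_range = parameter_range,
                     fit_method = fit_method, metric = xmin_distance)
    scan <- sc$scan
    sel_xmin <- sc$xmin
    noise_flag <- sc$noise_flag
  }

  session <- structure(
    list(values = values,
         data = tail_filter(values, sel_xmin, xmax),
         discrete = discrete,
         xmin = sel_xmin, xmax = xmax,
         fixed_xmin = fixed_xmin, given_xmin = given_xmin,
         fixed_xmax = fixed_xmax,
         scan = scan, noise_flag = noise_flag,
         supported_distributions = supported_distributions(),
         options = list(estimate_discrete = estimate_discrete,
                        discrete_approximation = discrete_approximation,
                        sigma_threshold = sigma_threshold,
                        parameter_range = parameter_range,
                        fit_method = fit_method,
                        xmin_distance = xmin_distance),
         models = new.env(parent = emptyenv())),
    class = "heavy_fit"
  )
  # the power law is the anchor of the analysis; fit it eagerly
  fit_model(session, "power_law")
  session
}

#' Select the optimal scaling range of a sample
#'
#' Runs the candidate-xmin scan on its own and returns the selected lower
#' bound together with the full scan record. [heavy_fit()] calls this
#' internally; it is exposed for inspection of alternative local minima.
#'
#' @inheritParams heavy_fit
#' @param xmin_range optional `c(lo, hi)` restriction of the candidates.
#' @return a list with `xmin` (selected value), `scan` (data frame of
#'   candidates: `xmins`, the distance column named after the metric
#'   (`Ds`, `Vs` or `Asquares`), `alphas`, `sigmas`, `in_range`) and
#'   `noise_flag`.
#' @export
find_xmin <- function(values, discrete = FALSE, xmax = NULL,
                      estimate_discrete = TRUE, xmin_range = NULL,
                      sigma_threshold = NULL, parameter_range = NULL,
                      fit_method = c("ML", "KS"),
                      xmin_distance = c("D", "V", "Asquare")) {
  check_positive_values(values)
  scan_xmins(values, discrete = discrete, xmax = xmax,
             estimate_discrete = estimate_discrete, xmin_range = xmin_range,
             sigma_threshold = sigma_threshold,
             parameter_range = parameter_range,
             fit_method = match.arg(fit_method),
             metric = match.arg(xmin_distance))
}

scan_xmins <- function(values, discrete, xmax, estimate_discrete,
                       xmin_range, sigma_threshold, parameter_range,
                       fit_method, metric) {
  sv <- sort(values[if (is.null(xmax)) TRUE else values <= xmax])
  uv <- unique(sv)
  K <- length(uv)
  if (K < 2L) stop("need at least 2 unique values below xmax", call. = FALSE)
  cnt <- tabulate(match(sv, uv), nbins = K)
  cum <- cumsum(cnt)
  n_all <- cum[K]
  # suffix sums of log(x) for O(1) closed-form exponents
  rlog <- rev(cumsum(rev(cnt * log(uv))))

  alpha_bounds <- c(1 + 1e-8, ALPHA_MAX)
  predicate <- NULL
  sigma_bounds <- c(NA_real_, NA_real_)
  if (is.function(parameter_range)) {
    predicate <- parameter_range
  } else if (!is.null(parameter_range)) {
    if (!is.null(parameter_range$alpha)) {
      b <- parameter_range$alpha
      if (!is.na(b[1])) alpha_bounds[1] <- max(alpha_bounds[1], b[1])
      if (length(b) > 1 && !is.na(b[2])) alpha_bounds[2] <- b[2]
    }
    if (!is.null(parameter_range$sigma)) sigma_bounds <- parameter_range$sigma
  }

  idx <- seq_len(K - 1L)                     # leave at least one larger value
  idx <- idx[n_all - c(0, cum)[idx] >= 2L]   # >= 2 tail points
  if (!is.null(xmax)) idx <- idx[uv[idx] < xmax]
  if (!is.null(xmin_range)) {
    idx <- idx[uv[idx] >= xmin_range[1] & uv[idx] <= xmin_range[2]]
  }
  if (length(idx) == 0L) {
    stop("no candidate xmin values satisfy the search constraints",
         call. = FALSE)
  }

  m <- length(idx)
  alphas <- numeric(m); dists <- numeric(m); sigmas <- numeric(m)
  in_range <- logical(m)
  for (j in seq_len(m)) {
    i <- idx[j]
    xm <- uv[i]
    n_i <- n_all - (if (i > 1L) cum[i - 1L] else 0)
    slog <- rlog[i]
    ux <- uv[i:K]
    S_hi <- (cum[i:K] - (if (i > 1L) cum[i - 1L] else 0)) / n_i
    S_lo <- c(0, S_hi[-length(S_hi)])
    w <- cnt[i:K]

    dist_of <- function(a) {
      model <- heavy_dist("power_law", a, xmin = xm, xmax = xmax,
                          discrete = discrete)
      P <- dist_cdf(model, ux)
      # see metric_steps(): a discrete model's CDF jumps with the data, so
      # the left-side comparison uses the model CDF at the previous integer
      P_lo <- if (discrete) {
        c(0, if (length(ux) > 1L) dist_cdf(model, ux[-1L] - 1) else NULL)
      } else P
      switch(metric,
        D = max(pmax(abs(S_hi - P), abs(S_lo - P_lo))),
        V = max(0, S_hi - P, S_lo - P_lo) + max(0, P - S_hi, P_lo - S_lo),
        Asquare = {
          keep <- P > 0 & P < 1
          sum(w[keep] * (S_hi[keep] - P[keep])^2 / (P[keep] * (1 - P[keep])))
        })
    }

    a <- if (fit_method == "KS") {
      stats::optimize(dist_of, alpha_bounds, tol = 1e-8)$minimum
    } else if (!discrete && is.null(xmax)) {
      1 + n_i / (slog - n_i * log(xm))
    } else if (discrete && estimate_discrete && is.null(xmax)) {
      1 + n_i / (slog - n_i * log(xm - 0.5))
    } else if (discrete) {
      optimize_alpha_discrete(slog, n_i, xm, xmax,
                              alpha_bounds[1], alpha_bounds[2])
    } else {
      nll <- function(a) {
        -(n_i * (log(a - 1) - log(xm^(1 - a) - xmax^(1 - a))) - a * slog)
      }
      stats::optimize(nll, alpha_bounds, tol = 1e-10)$minimum
    }
    a <- min(max(a, alpha_bounds[1]), alpha_bounds[2])
    alphas[j] <- a
    sigmas[j] <- (a - 1) / sqrt(n_i)
    dists[j] <- dist_of(a)

    ok <- TRUE
    if (!is.null(sigma_threshold) && sigmas[j] > sigma_threshold) ok <- FALSE
    if (ok && !is.na(sigma_bounds[1]) && sigmas[j] < sigma_bounds[1]) ok <- FALSE
    if (ok && length(sigma_bounds) > 1 && !is.na(sigma_bounds[2]) &&
        sigmas[j] > sigma_bounds[2]) ok <- FALSE
    if (ok && !is.null(predicate)) {
      ok <- isTRUE(predicate(list(alpha = alphas[j], sigma = sigmas[j])))
    }
    in_range[j] <- ok
  }

  scan <- data.frame(xmins = uv[idx], dist = dists, alphas = alphas,
                     sigmas = sigmas, in_range = in_range)
  names(scan)[2] <- switch(metric, D = "Ds", V = "Vs", Asquare = "Asquares")

  noise_flag <- FALSE
  pool <- which(in_range)
  if (length(pool) == 0L) {
    warning("No valid fits found.", call. = FALSE)
    noise_flag <- TRUE
    pool <- seq_len(m)
  }
  best <- pool[which.min(dists[pool])]   # ties: smallest xmin (sorted order)
  list(xmin = uv[idx[best]], scan = scan, noise_flag = noise_flag)
}

#' Fit (and cache) one candidate family on a session's tail
#'
#' @param session a [heavy_fit()] object.
#' @param family one of `session$supported_distributions`.
#' @return the fitted [heavy_dist()] model. The power-law model
#'   additionally carries `sigma`, `D` and `method` entries. Models are
#'   computed on first access and cached on the session.
#' @export
fit_model <- function(session, family) {
  stopifnot(inherits(session, "heavy_fit"))
  family <- check_family(family)
  cached <- get0(family, envir = session$models, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  opts <- session$options
  pr <- opts$parameter_range
  model <- if (family == "power_law" && opts$fit_method == "ML") {
    alpha_range <- if (is.list(pr)) pr$alpha else NULL
    pf <- fit_power_law(session$data, xmin = session$xmin, xmax = session$xmax,
                        discrete = session$discrete,
                        estimate_discrete = opts$estimate_discrete,
                        alpha_range = alpha_range)
    d <- heavy_dist("power_law", pf$alpha, xmin = session$xmin,
                    xmax = session$xmax, discrete = session$discrete,
                    estimate_discrete = opts$estimate_discrete)
    d$sigma <- pf$sigma; d$D <- pf$D; d$method <- pf$method
    d
  } else {
    # predicate-form ranges constrain the power-law scan, not the other
    # family fits; box bounds apply wherever parameter names match
    fit_dist_mle(family, session$data, xmin = session$xmin,
                 xmax = session$xmax, discrete = session$discrete,
                 discrete_approximation = opts$discrete_approximation,
                 parameter_range = if (is.list(pr) || family == "power_law") pr
                   else NULL,
                 fit_method = opts$fit_method)
  }
  if (family == "power_law" && is.null(model$sigma)) {
    model$sigma <- (model$parameters[["alpha"]] - 1) / sqrt(length(session$data))
    model$D <- ks_distance(model, session$data)
  }
  assign(family, model, envir = session$models)
  model
}

#' Generic parameter access on a fitted model
#'
#' Positional access to fitted parameters (`parameter1`, `parameter2`, ...)
#' and their names, mirroring name-based access via `d$parameters`.
#'
#' @param d a [heavy_dist()] model.
#' @param i parameter position (1-based).
#' @return `parameter_n(d, i)` returns the value or `NULL` beyond the
#'   family's arity; `parameter_name(d, i)` the name or `NULL`.
#' @export
#' @examples
#' d <- heavy_dist("lognormal", c(0.5, 1.2), xmin = 1)
#' parameter_n(d, 1)      # 0.5
#' parameter_name(d, 2)   # "sigma"
parameter_n <- function(d, i) {
  stopifnot(inherits(d, "heavy_dist"))
  if (i > length(d$parameters)) return(NULL)
  unname(d$parameters[[i]])
}

#' @rdname parameter_n
#' @export
parameter_name <- function(d, i) {
  stopifnot(inherits(d, "heavy_dist"))
  if (i > length(d$parameters)) return(NULL)
  names(d$parameters)[i]
}

#' @export
print.heavy_fit <- function(x, ...) {
  pl <- fit_model(x, "power_law")
  cat("<heavy_fit>", if (x$discrete) "discrete" else "continuous",
      "sample of", length(x$values), "values\n")
  cat(sprintf("  xmin = %g (%s), xmax = %s\n", x$xmin,
              if (x$fixed_xmin) "fixed" else "optimized",
              if (is.null(x$xmax)) "Inf" else format(x$xmax)))
  cat(sprintf("  power law: alpha = %.4f, sigma = %.4f, D = %.4f (n_tail = %d)\n",
              pl$parameters[["alpha"]], pl$sigma, pl$D, length(x$data)))
  if (isTRUE(x$noise_flag)) cat("  noise_flag: TRUE\n")
  invisible(x)
}
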