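# Pairwise comparison of candidate distributions by loglikelihood ratio.
#
# The ratio R = sum_i [log p1(x_i) - log p2(x_i)] is positive when the
# data is more likely under the first candidate. For non-nested pairs the
# significance comes from the Vuong normalization: R divided by its
# estimated standard deviation times sqrt(n) is asymptotically standard
# normal, giving a two-sided p. When one family is a special case of the
# other (power law inside the exponentially truncated power law;
# exponential inside the stretched exponential), 2|R| is referred to a
# chi-squared distribution instead.

#' Per-point loglikelihood ratio between two models
#'
#' @param model1,model2 two [heavy_dist()] models sharing a support.
#' @param tail_data data within that support.
#' @return list with `R` (the summed ratio) and `diffs` (per-point log
#'   density differences).
#' @export
loglikelihood_ratio <- function(model1, model2, tail_data) {
  stopifnot(inherits(model1, "heavy_dist"), inherits(model2, "heavy_dist"))
  if (length(tail_data) == 0L) stop("empty data", call. = FALSE)
  lp1 <- dist_logpdf(model1, tail_data)
  lp2 <- dist_logpdf(model2, tail_data)
  if (any(!is.finite(lp1))) {
    stop("zero probability under the first (", model1$family, ") model",
         call. = FALSE)
  }
  if (any(!is.finite(lp2))) {
    stop("zero probability under the second (", model2$family, ") model",
         call. = FALSE)
  }
  diffs <- lp1 - lp2
  list(R = sum(diffs), diffs = diffs)
}

#' Vuong-normalized ratio and p-value
#'
#' Normalizes the loglikelihood ratio by its estimated standard deviation,
#' \eqn{R / (\hat\sigma \sqrt{n})} with
#' \eqn{\hat\sigma^2 = n^{-1} \sum_i (d_i - \bar d)^2}, and returns the
#' two-sided normal tail probability
#' \eqn{p = \mathrm{erfc}(|R_n| / \sqrt 2)}.
#'
#' @param diffs per-point loglikelihood differences from
#'   [loglikelihood_ratio()].
#' @return list with `normalized_R` and `p`.
#' @export
#' @examples
#' # a normalized ratio of 1.431 corresponds to p = 0.152
vuong_p <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  sigma2 <- mean((diffs - mean(diffs))^2)
  if (sigma2 <= 0) {
    stop("zero variance of the loglikelihood differences: ",
         "the models are indistinguishable on these data", call. = FALSE)
  }
  normalized_R <- sum(diffs) / (sqrt(sigma2) * sqrt(n))
  list(normalized_R = normalized_R,
       p = 2 * stats::pnorm(abs(normalized_R), lower.tail = FALSE))
}

#' Nested-model p-value for a loglikelihood ratio
#'
#' When one candidate is a special case of the other, twice the absolute
#' loglikelihood ratio is asymptotically chi-squared with degrees of
#' freedom equal to the difference in parameter count (1 for both nested
#' pairs shipped here).
#'
#' @param R loglikelihood ratio (sign is ignored).
#' @param dof_difference difference in number of parameters, at least 1.
#' @return the p-value \eqn{1 - F_{\chi^2}(2|R|; \mathrm{dof})}.
#' @export
#' @examples
#' nested_p(-0.3818) # 0.3821
nested_p <- function(R, dof_difference = 1) {
  if (dof_difference < 1) stop("dof_difference must be >= 1", call. = FALSE)
  stats::pchisq(2 * abs(R), df = dof_difference, lower.tail = FALSE)
}

#' Is one family a nested version of the other?
#'
#' Detection follows the canonical family names: a pair is nested when one
#' name is contained in the other (`power_law` inside
#' `truncated_power_law`, `exponential` inside `stretched_exponential`).
#'
#' @param family1,family2 family names from [supported_distributions()].
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' detect_nested("power_law", "truncated_power_law") # TRUE
detect_nested <- function(family1, family2) {
  check_family(family1)
  check_family(family2)
  if (family1 == family2) return(FALSE)
  grepl(family1, family2, fixed = TRUE) || grepl(family2, family1, fixed = TRUE)
}

#' Compare the goodness of fit of two candidate distributions
#'
#' Fits both families on the session's tail (via [fit_model()]), computes
#' the loglikelihood ratio, and derives the significance: the nested
#' chi-squared form when the pair is nested (auto-detected from the family
#' names, overridable with `nested`), the Vuong normal form otherwise. The
#' p-value of the non-nested test always comes from the normalized ratio;
#' `normalized_ratio` only selects which ratio is reported.
#'
#' @param session a [heavy_fit()] object.
#' @param family1,family2 candidate family names.
#' @param normalized_ratio report the Vuong-normalized ratio instead of
#'   the raw loglikelihood ratio.
#' @param nested override the automatic nestedness detection.
#' @return an object of class `heavy_compare`: a list with `family1`,
#'   `family2`, `R`, `normalized_R` (`NA` when the pair is nested), `p`,
#'   `nested`, `n`, and `ratio` (the reported ratio, per
#'   `normalized_ratio`).
#' @export
#' @examples
#' x <- dist_rand(heavy_dist("power_law", 2.5, xmin = 1), 500, seed = 1)
#' fit <- heavy_fit(x, xmin = 1)
#' distribution_compare(fit, "power_law", "exponential")
distribution_compare <- function(session, family1, family2,
                                 normalized_ratio = FALSE, nested = NULL) {
  stopifnot(inherits(session, "heavy_fit"))
  m1 <- fit_model(session, family1)
  m2 <- fit_model(session, family2)
  lr <- loglikelihood_ratio(m1, m2, session$data)
  is_nested <- if (is.null(nested)) detect_nested(family1, family2) else
    isTRUE(nested)
  if (is_nested) {
    message("Assuming nested distributions")
    p <- nested_p(lr$R)
    normalized_R <- NA_real_
  } else if (all(abs(lr$diffs) < 1e-12)) {
    # identical likelihoods point by point (e.g. a family compared with
    # itself): no evidence either way
    p <- 1
    normalized_R <- 0
  } else {
    v <- vuong_p(lr$diffs)
    p <- v$p
    normalized_R <- v$normalized_R
  }
  structure(
    list(family1 = family1, family2 = family2,
         R = lr$R, normalized_R = normalized_R, p = p, nested = is_nested,
         n = length(lr$diffs),
         ratio = if (normalized_ratio && !is_nested) normalized_R else lr$R),
    class = "heavy_compare"
  )
}

#' @export
print.heavy_compare <- function(x, ...) {
  cat(sprintf("Comparison %s vs %s%s\n", x$family1, x$family2,
              if (x$nested) " (nested)" else ""))
  cat(sprintf("  R = %.4f%s, p = %.4g  [n = %d]\n", x$R,
              if (!is.na(x$normalized_R))
                sprintf(", normalized R = %.4f", x$normalized_R) else "",
              x$p, x$n))
  invisible(x)
}
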