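---
title: "Methods: fitting and comparing heavy-tailed distributions"
author: "heavytail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitting and comparing heavy-tailed distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heavytail)
```

## The model and the analysis it supports

A power law is the density $p(x) = C x^{-\alpha}$ on $x \ge x_{min} > 0$,
with $C = (\alpha - 1) x_{min}^{\alpha - 1}$ when no upper bound is
present. Because the density diverges at zero, every power-law claim is a
claim about a *tail*: the analysis must decide where scaling begins
($x_{min}$), estimate the exponent on the data above it, and then ask
whether a power law describes that tail better than other heavy-tailed
candidates. `heavytail` implements the three steps as:

1. **Exponent estimation.** For continuous data with no upper bound the
   maximum likelihood estimator is analytic,
   $\hat\alpha = 1 + n\left[\sum_i \ln(x_i/x_{min})\right]^{-1}$, with
   standard error $\sigma = (\hat\alpha - 1)/\sqrt{n}$. With an upper
   bound $x_{max}$, or for the exact discrete form (normalized by the
   Hurwitz zeta function $\zeta(\alpha, x_{min})$), the likelihood is
   maximized numerically. For discrete data an analytic approximation
   replaces $x_{min}$ with $x_{min} - 1/2$; it is accurate to about 1%
   for $x_{min} \ge 6$, which the validation harness
   (`discrete_estimator_error()`) verifies by simulation.
2. **Scaling-range selection.** A power law is fitted starting at every
   unique data value, and the start minimizing the Kolmogorov–Smirnov
   distance between the empirical and fitted CDFs is selected
   (`heavy_fit()` with free `xmin`). The per-candidate record (distances,
   exponents, standard errors, constraint status) is retained in
   `fit$scan` so alternative local minima can be inspected.
3. **Comparison.** Two fitted candidates are compared by the
   loglikelihood ratio $R = \sum_i [\ln p_1(x_i) - \ln p_2(x_i)]$. For
   non-nested pairs, $R/(\hat\sigma\sqrt n)$ with
   $\hat\sigma^2 = n^{-1}\sum_i (d_i - \bar d)^2$ is asymptotically
   standard normal under the null of equal fit quality, giving a
   two-sided p. When one family contains the other as a special case the
   ratio cannot favor the smaller family, and $2|R|$ is instead referred
   to a $\chi^2_1$ distribution.

All six families are defined over the truncated support
$[x_{min}, x_{max}]$; the stretched exponential uses the
parameterization $p(x) = \beta\lambda x^{\beta-1}
e^{-\lambda(x^\beta - x_{min}^\beta)}$, stated here explicitly because
Weibull conventions differ between sources. The exponentially truncated
power law's normalizer is
$\lambda^{1-\alpha}\,\Gamma(1-\alpha, \lambda x_{min})$, an upper
incomplete gamma function with a *negative* first argument; no installed
R routine evaluates that case, so the package implements it directly (a
convergent power series below $x = 7$, a Lentz-evaluated continued
fraction above) and the test suite pins it against numeric quadrature.
The Hurwitz zeta function is likewise computed in-package by direct
summation plus an Euler–Maclaurin tail correction with Bernoulli terms
through $B_8$, giving roughly $10^{-12}$ relative accuracy over the
fitting range; tests compare it to brute-force summation.

## Assumptions

Maximum likelihood fitting and the ratio tests assume independent
observations. Correlated data (e.g. spatially clustered observations)
can bias both the fit and the comparison; the package does not attempt
automatic decorrelation — thinning the data to an approximately
independent subset is the user's responsibility. Minimum-distance
estimation (`fit_method = "KS"`), which fits parameters by minimizing
the Kolmogorov–Smirnov distance instead of the likelihood, is available
but does not repair the independence assumption for comparisons.

## Tunable parameters

* `xmin` (same units as the data): fixed value, search range
  `c(lo, hi)` (inclusive; selected candidates are always actual data
  values), or `NULL` for a free search. Candidates leaving fewer than
  two tail points are excluded, since neither the MLE nor its standard
  error exists below that.
* `xmax`: optional upper bound; data above it is ignored for fitting.
  Useful for finite-size-limited observations. With an `xmax`, CDF and
  CCDF curves bend down on log-log axes as the bound is approached while
  the PDF stays straight, so PDFs are the better visual check there.
* `discrete` / `estimate_discrete`: integer data use the exact
  zeta-normalized power law; `estimate_discrete = TRUE` (default)
  selects the fast analytic exponent estimate during fitting and the
  fast transform during generation. The same estimator choice is used
  inside the `xmin` scan as in the final fit, for speed/accuracy
  symmetry. The fast generator's error falls with `xmin` (about 1% at
  `xmin = 5`); for smaller `xmin` prefer `estimate_discrete = FALSE`.
* `discrete_approximation`: discrete flavors of families without an
  analytic discrete form. `"round"` (default) sums the continuous kernel
  over half-integer bins, with the lowest bin edge at `xmin - 1/2` —
  symmetric rounding, chosen so the rounding bins partition the support
  consistently with the `xmin - 1/2` shift in the analytic discrete
  estimate. Brute-force alternatives (`"xmax"` or a numeric limit)
  normalize kernel values on an integer grid; a limit is required when
  no `xmax` exists, and the package refuses to invent one.
* `sigma_threshold` and `parameter_range`: constraints applied during
  the scan. Bound-type ranges on `alpha` steer each candidate fit to the
  constraint boundary (the likelihood is concave in `alpha`, so the
  constrained optimum is the clamped closed form); ranges on `sigma` and
  predicate functions mark candidates as out of range after fitting.
  When no candidate is admissible the constraints are dropped, the
  global minimum is selected, the session's `noise_flag` is set, and
  "No valid fits found." is warned.
* `xmin_distance`: `"D"` (default), `"V"` (Kuiper), `"Asquare"`. The
  Anderson–Darling form implemented is the plug-in sum
  $\sum_i (S(x_i)-P(x_i))^2/(P(x_i)(1-P(x_i)))$ over data points with
  endpoint terms dropped — not the classical rank formula, which is tied
  to fully specified continuous nulls. This choice keeps the statistic
  defined for every fitted model, and it inherits the known conservatism
  of tail-weighted selection: it tends to push `xmin` high and keep few
  tail points, so it is exposed but not the default.

## Numerical choices

* Numerical likelihood maximization uses derivative-free methods on the
  penalized negative loglikelihood: Brent line search for one-parameter
  families (bracketed around the data-driven guess and widened while the
  optimum touches an edge) and Nelder–Mead (relative tolerance $10^{-8}$)
  for two-parameter families. Box constraints enter through a large
  smooth penalty. Initial guesses come from the data: log-moments for
  the lognormal, $1/(\bar x - x_{min})$ for the exponential (also the
  stretched exponential with $\beta = 1$), the continuous power-law
  closed form with a small $\lambda$ for the truncated power law, and
  moment matching for the gamma.
* If the initial guess lies outside a user-supplied parameter range, the
  search would start on the flat penalty plateau with no likelihood
  signal, so the guess is projected into the range and returned with
  `noise_flag = TRUE`; supplying `initial_parameters` inside the range
  restores a clean search. This mirrors the fallback in the scan.
* Likelihoods, normalizers and tail probabilities are computed on the
  log scale throughout, so deep-tail points never underflow into
  spurious zero-probability errors; a zero-probability error is reserved
  for structural zeros (e.g. a point beyond a brute-force limit).
* The Kolmogorov–Smirnov distance is the exact supremum of
  $|S - P|$: for continuous models the empirical step is evaluated from
  both sides at each data point; for discrete models — whose model CDF
  jumps at the same integers — the left-side comparison instead pairs
  the empirical value below a point with the model CDF at the preceding
  integer, which also covers unobserved integers inside gaps. A naive
  two-sided evaluation against a discrete CDF would inflate D by the
  mass at `xmin` and systematically mis-select the scaling range.
* Ties in the scan (equal minimal distance) resolve to the smallest
  `xmin`, retaining the most data.
* Degenerate inputs fail fast with classed errors: all tail points equal
  to `xmin` (the MLE diverges), fewer than two unique values, empty
  data, non-integer data declared discrete.
* Random generation inverts closed-form CDFs where they exist. The
  continuous truncated power law is sampled by rejection from the pure
  power law with acceptance $e^{-\lambda(x - x_{min})}$ — exact, and
  efficient when $\lambda x_{min}$ is small (acceptance degrades as
  $e^{-\lambda x_{min}}$ grows; for strongly truncated regimes the
  numeric quantile path `dist_quantile()` is the alternative). Exact
  discrete generation returns the smallest integer whose CDF reaches the
  uniform draw, located by vectorized doubling plus binary search on the
  analytic discrete CDF.
* Every stochastic entry point takes an explicit `seed` and restores the
  caller's RNG state, so identical seeds give identical streams
  end-to-end (generation, fitting, comparison, validation reports).

## What the synthetic data does and does not emulate

The generators draw i.i.d. samples from the exact theoretical families,
including the study conditions used by the validation harness: 10,000
points per dataset with 10 replicates per parameter cell for the
headline accuracy figures (`scripts/acceptance.R`), and a scaled-down
default of 2,000 points with 3 replicates in `recovery_grid()` for
routine runs — sizes chosen so a full validation completes in minutes on
one CPU while the Monte Carlo error stays a small fraction of the
tolerances being checked. Because simulated samples contain no values
below the true `xmin`, the recovered `xmin` can only err upward on clean
data, and the harness reports the fraction of replicates respecting that
one-sided property (it should be 1). Real data differ in ways the
simulations deliberately omit: sub-`xmin` noise (which in practice makes
`xmin` recovery *easier*, by giving the scan something to exclude),
correlations between observations, measurement rounding, and finite
observation windows. Passing the simulation suite therefore demonstrates
correctness of the estimators and their implementations, not that any
particular empirical dataset is power-law distributed.

The Vuong-calibration check in the test suite constructs its null by
symmetry: data from a lognormal are compared under two fixed candidate
lognormals placed symmetrically about the truth in log space, which have
exactly equal Kullback–Leibler divergence from the generating model.
Fitted pairs of distinct flexible families are never exactly
equidistant, so they cannot serve as a clean null.

## Other design decisions

* The nested-pair degrees of freedom default to 1 because both shipped
  nested pairs (power law ⊂ truncated power law, exponential ⊂ stretched
  exponential) add exactly one parameter; `nested_p()` exposes
  `dof_difference` for extensions.
* Non-nested p-values are always computed from the *normalized* ratio;
  the `normalized_ratio` flag only selects which ratio is reported
  alongside them. Reporting is therefore consistent between the raw and
  normalized views of the same comparison.
* Nestedness detection is an exact substring relation on the canonical
  family registry, never on free text; an explicit `nested` argument
  always wins.
* Under `fit_method = "KS"` the `xmin` scan fits each candidate by the
  same minimum-distance criterion as the final fit, keeping the selected
  range consistent with the estimator that will be reported.
* `sigma` is reported as $(\alpha-1)/\sqrt{n}$ for *all* power-law
  flavors, including discrete and `xmax`-truncated fits where it is only
  an approximation to the observed-information standard error; the exact
  alternative is out of scope and the approximation is documented here.
  Non-power-law families carry no `sigma`: no analogous closed form
  exists, and inventing one would suggest false precision.
* Log-binned PDFs default to 10 bin edges per decade anchored at powers
  of 10, rounded outward so every observation falls in a bin; empty bins
  are kept in the returned structure (so densities integrate to one) but
  suppressed from log-log plots, where zero has no logarithm. The
  empirical CCDF uses the inclusive convention $P(X \ge x)$, keeping the
  largest observation visible on log axes; consequently
  $\mathrm{cdf}(x) + \mathrm{ccdf}(x) = 1 + P(X = x)$ at observed
  points.

## Known limitations

* Goodness-of-fit is assessed *comparatively* (likelihood ratios between
  candidates), not absolutely: the package deliberately provides no
  bootstrapped p-value for "is this exactly a power law", a question
  that any noisy empirical dataset fails at sufficient sample size.
* The rejection sampler for the continuous truncated power law slows
  down as $\lambda x_{min}$ grows large.
* Brute-force discretization truncates the support at its limit; points
  beyond it have structurally zero mass and will fail likelihood
  evaluation, which is the intended signal to raise the limit.
* The free-`xmin` scan is quadratic in the number of unique values
  (each candidate's distance needs its tail); about 10,000 unique values
  fit comfortably in seconds, hundreds of thousands will not.
* Fits with user parameter ranges far from the likelihood optimum return
  flagged fallbacks rather than searching exhaustively; this is a
  deliberate trade of completeness for predictability.
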