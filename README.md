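# heavytail

Statistically rigorous fitting and comparison of heavy-tailed
distributions in R.

Empirical quantities from many domains — word frequencies, neuronal
avalanche and connectivity degree distributions, blackout sizes — have
right tails far heavier than an exponential, and are often summarized by a
power law

    p(x) ∝ x^(−α),   x ≥ xmin.

Deciding whether that summary is justified is not a matter of fitting a
straight line to a log-log histogram. It requires (i) maximum likelihood
estimation of α on a scaling range, (ii) a principled choice of where the
scaling range starts, and (iii) likelihood-based comparison against other
heavy-tailed candidates. `heavytail` implements that full workflow for
both continuous and discrete (integer) data:

* **Six candidate families** over a truncated support `[xmin, xmax]`:
  power law, exponential, stretched exponential (Weibull), lognormal,
  exponentially truncated power law, and gamma — each in continuous and
  discrete flavors (discrete forms by exact Hurwitz-zeta normalization
  for the power law, and by half-integer rounding or brute-force
  summation for the rest).
* **Scaling-range selection**: a power law is fitted starting from every
  unique value in the data and the `xmin` minimizing the
  Kolmogorov–Smirnov distance D is selected (Kuiper V and
  Anderson–Darling A² are available via `xmin_distance`), with optional
  `sigma_threshold` and `parameter_range` constraints and a `noise_flag`
  fallback when no candidate satisfies them.
* **Model comparison**: pairwise loglikelihood ratios
  R = Σᵢ [ln p₁(xᵢ) − ln p₂(xᵢ)], with the Vuong normalization
  R/(σ̂√n) and its two-sided normal p-value for non-nested pairs, and the
  chi-squared p-value on 2|R| for nested pairs (power law ⊂ truncated
  power law, exponential ⊂ stretched exponential), auto-detected from the
  family names.
* **Random generation**: inverse-CDF transforms, rejection sampling for
  the truncated power law, and for discrete power laws either a fast
  approximate transform or an exact search on the discrete CDF.
* **Visualization**: logarithmically binned PDFs and binning-free
  CDF/CCDF point sets, with thin base-graphics plot wrappers for data,
  fits, and theoretical curves.
* **Validation harness**: seeded simulation studies that refit generated
  data across parameter grids and quantify the accuracy of the fast
  discrete approximations.

## Worked example

Simulate a continuous power law (α = 2.5, xmin = 5), then recover the
parameters without telling the fit where the tail starts:

```r
library(heavytail)

theoretical <- heavy_dist("power_law", 2.5, xmin = 5)
data <- dist_rand(theoretical, 10000, seed = 1)

fit <- heavy_fit(data)
#> Calculating best minimal value for power law fit
fit
#> <heavy_fit> continuous sample of 10000 values
#>   xmin = 5.29471 (optimized), xmax = Inf
#>   power law: alpha = 2.4837, sigma = 0.0155, D = 0.0076 (n_tail = 9137)
```

The selected `xmin` (5.29) sits just above the true value — on clean
simulated data the KS scan can only err upward, because no sample values
exist below the true bound — and the exponent is recovered to well within
its standard error σ = (α−1)/√n. Is the power law actually a better
description than the alternatives?

```r
distribution_compare(fit, "power_law", "exponential", normalized_ratio = TRUE)
#> Comparison power_law vs exponential
#>   R = 3090.5861, normalized R = 8.3134, p = 9.303e-17  [n = 9137]

distribution_compare(fit, "power_law", "truncated_power_law")
#> Assuming nested distributions
#> Comparison power_law vs truncated_power_law (nested)
#>   R = -1.3284, p = 0.1031  [n = 9137]

distribution_compare(fit, "power_law", "lognormal")
#> Comparison power_law vs lognormal
#>   R = -0.5796, normalized R = -0.5887, p = 0.5561  [n = 9137]
```

Positive R favors the first candidate: the power law crushes the
exponential (the minimum bar for calling data heavy-tailed), while
neither the truncated power law nor the lognormal is distinguishable from
it on these data — exactly the right answer for a sample that *is* a pure
power law. Plotting works the same way on data, fits and models:

```r
plot_ccdf(fit, col = "red")
plot_ccdf(fit_model(fit, "power_law"), add = TRUE, lty = 2)
```

A command-line front end with the same capabilities is installed as
`exec/heavytail` (`heavytail fit data.txt --discrete --format json`, plus
`compare`, `simulate` and `validate` subcommands).

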