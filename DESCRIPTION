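Package: heavytail
Title: Fitting and Comparing Heavy-Tailed Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistically rigorous analysis of heavy-tailed data: maximum
    likelihood fits of power-law, lognormal, exponential, stretched
    exponential, truncated power-law and gamma distributions over a
    truncated support (continuous or discrete), automatic selection of the
    scaling range by Kolmogorov-Smirnov (or Kuiper / Anderson-Darling)
    distance minimization, pairwise model comparison by Vuong
    loglikelihood-ratio tests with the nested-model chi-squared correction,
    random variate generation including an exact search algorithm for
    discrete distributions, logarithmic binning for visualization, and a
    self-contained simulation-based validation harness. A command-line
    front end is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
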