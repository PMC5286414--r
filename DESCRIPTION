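Package: nichehull
Title: Generalized Layman Metrics and Resampling Confidence Intervals for
    n-Dimensional Niche Space
Version: 0.1.0
Authors@R: person("Ohio River", "Metrics Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Community-wide dispersion metrics for ecological niche space in
    any number of dimensions: per-axis ranges, mean distance to the centroid,
    mean and standard deviation of nearest neighbor distances, and convex
    hull volume, computed on taxon-mean coordinates such as stable isotope
    ratios, compound-specific amino-acid signatures, trophic positions or
    mixing-model diet fractions. Confidence intervals are attached by a
    non-parametric bootstrap over individual-level measurements or by
    parametric truncated-normal resampling of mean/SD estimate tables, and
    communities are compared by confidence-interval overlap. Includes
    amino-acid trophic-position calculators, a synthetic scenario generator,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
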