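Package: elebench
Title: Ecological Benchmarks for Savanna Elephant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to estimate environmentally mediated stable densities of
    savanna elephant populations from count time series via growth-model
    selection (null, linear, exponential, logistic, Gompertz; AICc), to model
    poaching intensity (PIKE, the proportion of illegally killed elephants)
    with averaged quasi-binomial GLMs, to relate stable population sizes to
    primary productivity (EVI), water availability and PIKE through a
    negative-binomial generalized additive model with a log-area offset, and
    to predict per-protected-area ecological benchmark population sizes under
    a zero-poaching scenario with nested Monte Carlo prediction intervals and
    deficit accounting. Includes a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
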