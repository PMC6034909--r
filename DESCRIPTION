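Package: vjpinfer
Title: Bayesian Parameter Inference for Velocity Jump Process Models of
    Biological Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of velocity jump (run-and-reorient) processes and
    exact Bayesian inference for their parameters from discretely and noisily
    observed single-particle tracks. Observed angle changes are modelled in a
    hidden-states framework with closed-form circular emission densities,
    convolved with wrapped-normal measurement noise. The marginal likelihood
    is estimated with a bootstrap particle filter and posteriors for the
    reorientation rate and noise amplitude are sampled by particle MCMC
    (pseudo-marginal Metropolis-Hastings), with rejection ABC using summary
    statistics available for comparison. Includes utilities for the
    sampling-interval versus noise experimental-design trade-off under a
    photon budget, and consensus Monte Carlo combination of per-track
    subposteriors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
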