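Package: icrgmm
Title: Residual-Based Class Enumeration for Growth Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum-likelihood estimation of latent growth curve models
    (linear and latent-basis), Bartlett factor scores and per-factor
    individual case residuals, a communality-normalized closeness measure,
    and an iterative residual-based algorithm that assigns individuals to
    latent trajectory classes and determines the number of classes directly
    from the data. Includes a Monte Carlo simulation engine for K-class
    mixtures of linear growth trajectories with controlled Mahalanobis
    class separation, and a study harness that estimates class-enumeration
    performance rates over a grid of design conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
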