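Package: evkf
Title: Online Variational Kalman Filtering in Exponential Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Online recursive variational Bayesian filtering for state-space
    models whose latent transitions live in a constant base measure exponential
    family (Gaussian, continuous Bernoulli, Gamma). Implements the
    exponential-family variational Kalman filter: a closed-form variational
    prediction step (expected natural parameters of the dynamics under the
    previous filtering posterior), an EKF-like variance correction, conjugate
    or natural-gradient (CVI) variational updates for Gaussian and Poisson
    observations, and simultaneous online learning of the latent dynamics by
    natural-parameter matching. Ships exact Kalman, extended Kalman, bootstrap
    particle and ensemble Kalman filter baselines; simulators for chaotic
    recurrent network, Van der Pol and continuous Bernoulli systems; and
    evaluation metrics (filtering log density, one-step dynamics KL, symmetric
    log Chamfer distance, RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
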