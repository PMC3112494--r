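Package: bmr
Title: Post Hoc Bayesian Model Reduction Under the Laplace Approximation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the evidence (marginal likelihood) and posterior of any
    reduced model -- a model sharing a full model's likelihood but with a
    different Gaussian prior -- in closed form from a single inversion of the
    full model, under the Laplace (Gaussian) approximation. Supports
    Savage-Dickey point-mass reductions, exhaustive and greedy searches over
    discrete model spaces defined by binary switch priors, continuous prior
    (hyperparameter) optimization including automatic relevance determination,
    a variational-Laplace inverter for general linear models with group-wise
    noise log-precisions, and a linear stochastic-network discovery
    demonstration. Includes a command-line interface for scripted pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils, tools, grDevices, graphics
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
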