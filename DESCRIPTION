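Package: urgencyddm
Title: Time-Variant Gain Drift-Diffusion Models of Choice and Response Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting and comparing drift-diffusion models of
    two-alternative perceptual decisions in which a logistic time-variant
    gain (urgency) signal multiplies the drift rate, the noise term, or
    both. Provides a Crank-Nicolson Fokker-Planck solver for first-passage-
    time densities between absorbing boundaries, Euler-Maruyama Monte-Carlo
    simulation, robust-likelihood multi-run fitting by differential
    evolution, AIC and squared-error model comparison with Kruskal-Wallis
    and Tukey HSD tests, and generators for species-like synthetic
    choice/response-time datasets (rat-like, monkey-like, human-like).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
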