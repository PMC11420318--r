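Package: levydm
Title: Levy-Flight Evidence-Accumulation Models of Two-Choice Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, likelihood approximation, amortized simulation-based
    fitting, and information-criterion comparison for Levy-Flight (LF)
    sequential-sampling models of two-choice decision making. The LF model
    generalizes the diffusion decision model by replacing Gaussian
    within-trial accumulation noise with symmetric alpha-stable noise,
    allowing sudden large jumps in accumulated evidence; the Gaussian model
    is recovered at stability index alpha = 2. The package provides an exact
    Chambers-Mulligan-Stuck sampler and characteristic-function densities for
    the stable noise, a forward trial simulator with between-trial parameter
    variability, a space-fractional Fokker-Planck solver (shifted
    Grunwald-Letnikov discretization of the Riesz derivative) for survival
    and first-passage-time densities, a convolutional regression network for
    amortized parameter estimation with a rejection-ABC fallback, AIC/BIC
    model comparison across five model variants, and a generator of
    study-shaped synthetic practice data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
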