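Package: magnetochain
Title: Magnetosome Chain Segregation Dynamics, Partitioning Statistics
    and Photokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying how magnetotactic bacteria
    position, split and segregate their magnetosome chains. Provides a
    stochastic one-dimensional overdamped simulator of magnetosome chain
    assembly and pole-to-midcell repositioning (midcell-directed active
    transport with a linear force-velocity relation, diffusion, magnetic
    dipole attraction and steric exclusion); partition-accuracy statistics
    built on an exponentially suppressed cumulative distribution of daughter
    chain fractions with a Kolmogorov-Smirnov test against the random
    splitting null; single-particle-track statistics (cumulative
    displacement, mean-square displacement, apparent diffusion coefficient,
    windowed velocity); FRAP and photoconversion normalization and
    single-exponential kinetic fitting; kymograph front-line treadmilling
    speed estimation; and seeded synthetic-data generators so every
    estimator can be exercised without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
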