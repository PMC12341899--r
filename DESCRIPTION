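Package: migstats
Title: Nonlinear Statistical Analysis of Single-Cell Migration Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for single-cell migration trajectories
    recorded by time-lapse tracking: root-mean-square-fluctuation (rmsf)
    analysis of move-step series with long-range correlation exponents and
    correlation times, time-averaged mean squared displacement (MSD) with
    anomalous-diffusion exponents, detrended fluctuation analysis (DFA),
    approximate entropy (ApEn) with growing-window profiles, kinematic
    descriptors (displacement cosine, sector histograms, intensity of
    response, directionality ratio, average speed), shuffled-surrogate
    nulls, and nonparametric cohort comparison.  Includes a synthetic
    motion generator (ballistic, Brownian, persistent correlated walks,
    fractional Gaussian noise step series) that emulates the statistical
    structure of galvanotaxis/chemotaxis experiments so every stage is
    verifiable without raw tracking data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
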