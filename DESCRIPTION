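Package: statedyn
Title: Discrete Brain-State Dynamics and Test-Retest Reliability for ROI fMRI Time Series
Version: 0.1.0
Authors@R: person("statedyn", "maintainers", email = "statedyn@example.org", role = c("aut", "cre"))
Description: Estimates discrete brain states from region-of-interest (ROI) fMRI
    time series by clustering volumes (K-means, K-medoids, Ward agglomerative,
    AAHC, TAAHC, bisecting K-means, Gaussian mixtures), scores clusterings by
    global explained variance and within-cluster sum of squares, computes
    state-transition observables (centroids, coverage, frequency, lifespan,
    transition probability matrix), matches states across sessions, and tests
    within- versus between-participant reliability of the dynamics with a
    normalized-distance (ND) permutation test. Includes a synthetic
    multi-participant, multi-session study generator with latent Markov state
    dynamics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
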