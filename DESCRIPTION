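Package: specdiff
Title: Spectral Differentiation of Neural Spiking Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neurophysiological differentiation (ND)
    of spiking neural populations: spike trains are binned, smoothed into
    firing rates, divided into analysis windows and state windows, and the
    median pairwise Euclidean distance between concatenated power-spectral-
    density state vectors is computed as the spectral differentiation of the
    ensemble. Includes per-ensemble normalization and analytic bounds, a
    mean-firing-rate control metric, stimulus (pixel-level) differentiation,
    trial-locked evoked differentiation, characteristic-timescale estimation
    from piecewise-constant signals and from two-exponent autocorrelation
    fits, timescale surveys with optimal-timescale detection and power-law
    fits, group comparisons with Games-Howell pairwise tests and
    Benjamini-Hochberg correction, and a synthetic-data generator producing
    stimuli, inhomogeneous Poisson spike trains, jittered virtual-neuron
    ensembles, and change-detection sessions with hit/miss outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
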