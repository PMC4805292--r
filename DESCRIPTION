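Package: pmfkd
Title: Umbrella-Sampling Free-Energy Profiles and Channel-Blocker Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs one-dimensional potential-of-mean-force (PMF)
    profiles from umbrella-sampling timeseries with the weighted histogram
    analysis method (WHAM), and converts a PMF into a standard dissociation
    constant for a pore blocker confined to a sampling cylinder of radius R
    via Kd^-1 = pi R^2 N_A Integral exp[-W(z)/kT] dz. Includes the companion
    statistical machinery: an autocorrelation-based decorrelation rule (1/e
    lag), bootstrap PMF uncertainty from resampled pseudo-datasets, and a
    data-fraction convergence diagnostic on the profile depth. A compiled
    overdamped Langevin simulator generates umbrella-window timeseries from
    known ground-truth potentials so every estimator can be validated against
    exact references. Plain-text file formats (timeseries, window metadata,
    PMF tables) and a command-line driver compose the steps end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
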