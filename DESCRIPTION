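Package: neuroethogram
Title: Discrete Neural-State Segmentation of Population Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of simultaneously recorded spike
    trains into discrete population states: binned counts are reduced to
    smooth latent trajectories with Gaussian-process factor analysis
    (GPFA), segmented with a sticky Gaussian-emission hidden Markov model
    fitted by MAP-EM with restarts, and the resulting state sequences are
    compared to tagged behavior with permutation tests on mutual
    information, bootstrap conditional probabilities with Holm-Bonferroni
    correction, and supervised decoding baselines. States from
    independently fitted sessions are matched through time-warped
    occupancy profiles and the Hungarian algorithm. A generative
    simulator of state-structured sessions with imperfect behavioral
    tags makes the whole pipeline testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
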