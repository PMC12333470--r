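Package: syllakin
Title: Subsecond Behavioral Syllable Analysis for Open-Field Locomotion
Version: 0.1.0
Authors@R: person("Syllakin", "Developers", role = c("aut", "cre"),
    email = "maintainers@syllakin.org")
Description: Segmentation of rodent keypoint trajectories into subsecond
    behavioral syllables with a sticky autoregressive hidden Markov model
    (AR-HMM) fit by Gibbs sampling, plus the downstream kinematic and
    sequence statistics used in open-field locomotion studies: per-syllable
    velocity, usage with an expression filter, syllable durations,
    transition matrices, steady-state distributions, entropy rate,
    transition frequency, and nonparametric group comparisons
    (Kruskal-Wallis with Dunn's post hoc and Benjamini-Hochberg correction,
    Mann-Whitney U, ordinary least squares for delta-metric regressions).
    Includes a Markov-switching kinematic simulator of multi-animal
    open-field cohorts (control, parkinsonian, and velocity-rescued
    treatment conditions) with known ground truth, so the full pipeline is
    testable without behavioral videos.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
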