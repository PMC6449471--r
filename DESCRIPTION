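Package: kinencode
Title: Poisson Encoding Models of Limb Kinematics for Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits and evaluates Poisson-likelihood encoding models (generalized
    linear models, feedforward networks, and recurrent networks) that map
    limb-state kinematics -- hand position, joint angles, muscle lengths and
    their first derivatives -- to binned spike counts of somatosensory cortical
    neurons. Model quality is scored per neuron with the deviance-based
    pseudo-R2 under k-fold cross-validation. Includes a synthetic session
    generator (planar two-link arm, minimum-jerk reaching, configurable
    ground-truth tuning with Poisson spiking) so that feature-class
    comparisons, population-versus-individual fitting, data-size ablations and
    regularization sweeps can be run and verified end to end without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
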