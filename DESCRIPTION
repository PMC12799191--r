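Package: spinalsnn
Title: Spiking Neural Network Simulation of the Rodent Ankle-Flexor Reflex Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of a biologically constrained spiking
    neural network of the rodent tibialis anterior (TA) flexor reflex loop:
    muscle-spindle Ia/II afferent encoding of synthetic gait profiles,
    leaky integrate-and-fire afferent axons, conductance-based LIF and
    adaptive exponential (AdEx) interneuron and motoneuron models, GABAergic
    presynaptic inhibition with spillover-driven release gating, and
    neuromodulation protocols (spinal cord injury synapse scaling,
    body-weight support afferent scaling, epidural-style electrical
    stimulation, serotonergic leak-conductance modulation). Includes
    analysis tooling (population rates, burst detection, synthetic EMG,
    phase summaries, equivalence and permutation statistics) and a Bayesian
    hierarchical B-spline mixed model with an in-package No-U-Turn sampler
    for testing output equivalence across random seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    splines,
    utils,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
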