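Package: quadgait
Title: Spinal Central Pattern Generator Network Model of Quadruped Gaits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-limb spinal locomotor circuit in which each limb
    is controlled by a persistent-sodium half-center rhythm generator and the
    four generators are coupled by commissural interneurons and long
    propriospinal neurons under a graded brainstem drive. Provides the
    canonical connectome with population deletion and weight perturbation,
    an adaptive Runge-Kutta integrator with Ornstein-Uhlenbeck noise,
    flexion/extension event detection with circular phase statistics and
    operational gait classification (walk, trot, gallop, bound), and the
    experiment protocols built on top of them: bifurcation sweeps of the
    drive parameter with hysteresis detection, genetic deletion phenotyping,
    noise-driven coordination variability, abrupt drive and drive-independent
    gait transitions, and connection-weight robustness screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
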