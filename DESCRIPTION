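Package: emgstiff
Title: EMG-Driven Estimation of Joint, Muscle, and Tendon Stiffness
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An EMG-driven musculoskeletal model of the human triceps surae
    that estimates ankle torque together with stiffness at the joint, muscle,
    and tendon levels from electromyographic envelopes and ankle angles.
    Three Hill-type muscle-tendon units (medial and lateral gastrocnemius,
    soleus) with elastic tendons are driven through activation dynamics, a
    constant-moment-arm kinematic map, and a per-sample fiber-tendon force
    equilibrium solved by Brent's method; analytic derivatives of the
    constitutive curves yield closed-form tendon, fiber, and unit stiffness.
    Seven parameters per muscle-tendon unit, including scale factors for
    tendon stiffness and muscle passive stiffness, are calibrated by bounded
    simulated annealing against multi-level reference signals. A synthetic
    subject generator emulating sinusoidal ankle rotations with superimposed
    pseudo-random binary perturbations, sustained plantarflexor activity, and
    ground-truth reference profiles makes every stage testable without
    experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
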