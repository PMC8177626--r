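Package: saccade3d
Title: Optimal Open-Loop Control of 3D Saccades in a Tendon-Driven Eye Plant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a simplified tendon-driven three-degree-of-freedom eye
    plant (six elastic extraocular "muscles" actuated in antagonistic pairs by
    three motor drivers), identifies a local linear state-space approximation
    of the plant by subspace system identification under pseudo-random binary
    excitation, and plans open-loop saccades by quadratic-programming
    minimization of combinations of accuracy, energy, duration, torsion and
    static-force costs.  Includes exact and small-angle 3D rotational
    kinematics (quaternions and Euler-Rodrigues rotation vectors), batch
    saccade experiments, and population analyses of Listing's plane,
    main-sequence dynamics, trajectory straightness and component stretching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
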