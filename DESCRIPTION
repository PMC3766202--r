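Package: gaitfuse
Title: Hybrid Compass-Pendulum and Spring-Mass Simulation of Normal and
    Pathological Human Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the sagittal-plane centre-of-gravity trajectory of
    human walking as a hybrid dynamical system: a compass pendulum during
    single stance and a planar two-leg spring-mass system during double
    stance, switched at heel-strike and toe-off events.  Learned heel paths,
    represented as weighted Gaussian-basis mixtures over the normalized gait
    cycle, regularize the simulated trajectory, and hip and knee
    flexion-extension angles are recovered by a two-link inverse-kinematics
    rule with cyclic-coordinate-descent refinement.  Ships presets for
    normal gait, crouch gait and Parkinsonian gait (disease stages 2-4),
    trajectory-similarity metrics (Pearson correlation, discrete Frechet
    and Hausdorff distances), a 12-segment skeleton animator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
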