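Package: slipgait
Title: Neuromuscular Spring-Loaded Inverted Pendulum Walking Simulator
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates sagittal-plane bipedal walking with a rigid trunk riding
    on two massless spring legs (the bipedal trunk spring-loaded inverted
    pendulum, BTSLIP), balanced at the hip either by force-modulated compliant
    hip springs (FMCH) or by an antagonistic pair of Hill-type hip muscles
    (rectus femoris and hamstrings) driven by delayed positive leg-force
    reflexes (the neuromuscular FMCH, nmF). Provides a hybrid event-driven
    integrator with touchdown/takeoff/mid-stance detection, velocity-based
    swing-leg placement, Poincare-map limit-cycle search and linearization, a
    discrete LQR layer that adapts the reflex gains once per step, perturbation
    and recovery experiments, basin-of-attraction sweeps, virtual-pivot-point
    estimation from simulated ground reaction forces, and stride-level energy
    accounting, with tidy tabular outputs and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
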