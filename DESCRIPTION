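Package: sepsim
Title: Simulation and Feedback Control of Innate Immune Dynamics in Sepsis
Version: 0.1.0
Authors@R:
    person("sepsim", "maintainers", email = "maintainers@sepsim.org",
           role = c("aut", "cre"))
Description: A mechanistic ordinary-differential-equation model of the innate
    immune response to pathogen invasion (neutrophils, monocytes, M1 and M2
    macrophages, IL-6 and TGF-beta), together with IL-6-responsive Hill-type
    feedback controllers that actuate selected kinetic rates. Provides an
    adaptive Runge-Kutta integrator with pulse perturbations, acute/septic
    outcome classification, virtual-cohort global sensitivity scans, controller
    hyperparameter grid optimization, Latin-hypercube robustness analysis,
    secondary-infection stress testing, least-squares calibration to immune
    cell time courses, a synthetic time-course generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
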