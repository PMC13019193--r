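# Shared fixtures, all built in code.

nominal <- nominal_parameters()

# A frozen septic scenario: the nominal world rescaled by these factors is
# septic uncontrolled (pathogen blows up by day 8) and is rescued by the
# M1-clearance controller at (alpha = 10, n = 1, Kd = 0.2). Derived once from
# a seeded cohort scan and rounded; treated as a stated fixture.
septic_factors <- c(alpha1 = 8.3, alpha2 = 5.4, beta = 8.9, gamma1 = 5.5,
                    gamma2 = 8.5, gamma3 = 8.4, gamma4 = 0.36, gamma5 = 1.8,
                    delta1 = 2.0, delta2 = 2.1, delta3 = 3.5, mu1 = 6.5,
                    mu2 = 7.0, mu3 = 9.1, mu4 = 0.9, Kn = 3.9, Cmax = 5.8,
                    theta_eff = 3.2, kappa = 9.1)
septic_params <- scale_parameters(nominal, septic_factors)

invasion <- immune_state(pathogen = 20)

# small random-but-reproducible states/parameter sets for property loops
random_state <- function() {
  as_immune_state(stats::setNames(stats::runif(7, 0, 30), species_names()))
}
random_params <- function(base = nominal) {
  f <- stats::setNames(stats::runif(19, 0.2, 5), scan_parameter_names())
  scale_parameters(base, f)
}
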