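# Independent oracles. These deliberately avoid the package's C++ path: they
# are written against the pure-R derivatives() contract (or from scratch) so
# that integrate_model() is checked by a genuinely different route.

# fixed-step classical RK4 on the R-level right-hand side, with the same
# nonnegativity projection as the production integrator
rk4_fixed_step <- function(params, initial, horizon, dt,
                           controller = NULL) {
  nstep <- round(horizon / dt)
  stopifnot(abs(nstep * dt - horizon) < 1e-9)
  y <- unclass(as_immune_state(initial))
  f <- function(y) {
    s <- as_immune_state(pmax(y, 0))
    m <- if (is.null(controller)) NULL else multipliers_for_state(s, controller)
    unclass(derivatives(s, params, rate_multipliers = m))
  }
  out <- matrix(NA_real_, nstep + 1, 7,
                dimnames = list(NULL, species_names()))
  out[1, ] <- y
  for (i in seq_len(nstep)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- pmax(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    out[i + 1, ] <- y
  }
  list(times = seq(0, horizon, by = dt), states = out)
}

# hand-expanded right-hand side, written out term by term independently of
# derivatives(); used for the multiplier-homogeneity check
rhs_hand_expanded <- function(s, p, m = c(mu3 = 1, delta3 = 1, mu2 = 1,
                                          gamma3 = 1)) {
  P <- s[["pathogen"]]; N <- s[["neutrophil"]]; Mo <- s[["monocyte"]]
  M1 <- s[["M1"]]; M2 <- s[["M2"]]; IL6 <- s[["IL6"]]; TGF <- s[["TGFb"]]
  eff <- 2 / (1 + exp(-p[["kappa"]] * (M1 - p[["theta_eff"]]))) - 1
  cap <- max(0, 1 - (N + Mo + M1 + M2) / p[["Cmax"]])
  hill <- if (P > 0)
    P^p[["n_hill"]] / (P^p[["n_hill"]] + p[["Kn"]]^p[["n_hill"]]) else 0
  c(pathogen   = p[["alpha2"]] * M1 * P * eff -
                 p[["gamma4"]] * N * P -
                 m[["delta3"]] * p[["delta3"]] * P,
    neutrophil = p[["alpha1"]] * hill * cap -
                 p[["gamma5"]] * N * IL6 -
                 p[["mu1"]] * N,
    monocyte   = p[["gamma5"]] * N * IL6 -
                 p[["gamma2"]] * Mo -
                 m[["mu2"]] * p[["mu2"]] * Mo,
    M1         = p[["gamma2"]] * Mo -
                 m[["gamma3"]] * p[["gamma3"]] * M1 * TGF -
                 m[["mu3"]] * p[["mu3"]] * M1,
    M2         = m[["gamma3"]] * p[["gamma3"]] * M1 * TGF -
                 p[["mu4"]] * M2,
    IL6        = p[["beta"]] * N - p[["delta1"]] * IL6,
    TGFb       = p[["gamma1"]] * M1 * N - p[["delta2"]] * TGF)
}
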