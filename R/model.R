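#' Immune state vector
#'
#' A nonnegative named vector of the seven model species: pathogen,
#' neutrophil, monocyte, M1, M2, IL6, TGFb (all in a.u.).
#'
#' @param pathogen,neutrophil,monocyte,M1,M2,IL6,TGFb species levels (a.u.,
#'   each >= 0).
#' @return An object of class `immune_state` (named numeric vector, length 7).
#' @export
immune_state <- function(pathogen = 0, neutrophil = 0, monocyte = 0,
                         M1 = 0, M2 = 0, IL6 = 0, TGFb = 0) {
  s <- c(pathogen = pathogen, neutrophil = neutrophil, monocyte = monocyte,
         M1 = M1, M2 = M2, IL6 = IL6, TGFb = TGFb)
  validate_state(s)
}

#' @rdname immune_state
#' @param x named numeric vector or list with the seven species names.
#' @export
as_immune_state <- function(x) {
  x <- unlist(x)
  missing <- setdiff(species_names(), names(x))
  if (length(missing))
    stop("missing species: ", paste(missing, collapse = ", "), call. = FALSE)
  validate_state(x[species_names()])
}

validate_state <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(!is.finite(s)))
    stop("state components must be finite numbers", call. = FALSE)
  if (any(s < 0))
    stop("state components must be nonnegative", call. = FALSE)
  structure(as.double(s), names = species_names(), class = "immune_state")
}

#' Myeloid carrying-capacity factor
#'
#' Returns `1 - (neutrophil + monocyte + M1 + M2) / Cmax`, clamped below at 0:
#' past the carrying capacity, recruitment stops rather than turning into a
#' spurious negative flux.
#'
#' @param state an `immune_state` (or named vector with the seven species).
#' @param Cmax positive carrying capacity (a.u.).
#' @return Scalar in \[0, 1\].
#' @export
capacity <- function(state, Cmax) {
  if (!is.numeric(Cmax) || length(Cmax) != 1 || !is.finite(Cmax) || Cmax <= 0)
    stop("Cmax must be a positive scalar", call. = FALSE)
  s <- as_immune_state(state)
  total <- s[["neutrophil"]] + s[["monocyte"]] + s[["M1"]] + s[["M2"]]
  max(0, 1 - total / Cmax)
}

#' M1 effector switch
#'
#' Shifted logistic `2 / (1 + exp(-kappa (M1 - theta_eff))) - 1`, a strictly
#' increasing sigmoid in (-1, 1) that crosses 0 at the activation threshold.
#' Algebraically identical to `tanh(kappa (M1 - theta_eff) / 2)`, which is the
#' overflow-safe form used here.
#'
#' @param M1 M1 macrophage level (a.u.).
#' @param theta_eff activation threshold (a.u.).
#' @param kappa steepness (> 0, 1/a.u.).
#' @return Scalar (vectorized over `M1`) in (-1, 1).
#' @export
effector <- function(M1, theta_eff, kappa) {
  if (!is.numeric(kappa) || any(kappa <= 0))
    stop("kappa must be positive", call. = FALSE)
  if (anyNA(M1) || any(!is.finite(M1)))
    stop("M1 must be finite", call. = FALSE)
  tanh(kappa * (M1 - theta_eff) / 2)
}

#' Right-hand side of the immune dynamics
#'
#' Evaluates the time derivatives of the seven species under mass-action
#' kinetics: Hill-type, capacity-limited neutrophil recruitment; IL-6-coupled
#' neutrophil-to-monocyte hand-off; monocyte differentiation into M1;
#' TGF-beta-driven M1-to-M2 polarization; effector-gated M1--pathogen
#' interaction; neutrophil-mediated and intrinsic pathogen removal; first-order
#' cytokine and cell turnover.
#'
#' @param state an `immune_state`.
#' @param params a `model_parameters` set.
#' @param rate_multipliers optional named nonnegative multipliers on the
#'   actuated rates `mu3`, `delta3`, `mu2`, `gamma3` (controller actuation
#'   points); missing entries default to 1.
#' @return Named numeric vector of length 7: d(state)/dt, in a.u./day.
#' @export
derivatives <- function(state, params, rate_multipliers = NULL) {
  s <- as_immune_state(state)
  p <- as_model_parameters(params)
  m <- c(mu3 = 1, delta3 = 1, mu2 = 1, gamma3 = 1)
  if (!is.null(rate_multipliers)) {
    if (is.null(names(rate_multipliers)) ||
        !all(names(rate_multipliers) %in% actuated_rates()))
      stop("rate_multipliers must be named by actuated rate (",
           paste(actuated_rates(), collapse = ", "), ")", call. = FALSE)
    if (any(rate_multipliers < 0) || anyNA(rate_multipliers))
      stop("rate multipliers must be nonnegative", call. = FALSE)
    m[names(rate_multipliers)] <- rate_multipliers
  }

  P <- s[["pathogen"]]; N <- s[["neutrophil"]]; Mo <- s[["monocyte"]]
  M1 <- s[["M1"]]; M2 <- s[["M2"]]; IL6 <- s[["IL6"]]; TGF <- s[["TGFb"]]

  eff <- effector(M1, p[["theta_eff"]], p[["kappa"]])
  cap <- capacity(s, p[["Cmax"]])
  # Hill recruitment with Kn as half-saturation concentration for any n
  Pn <- P^p[["n_hill"]]
  hill <- if (P > 0) Pn / (Pn + p[["Kn"]]^p[["n_hill"]]) else 0

  mu2 <- p[["mu2"]] * m[["mu2"]]
  mu3 <- p[["mu3"]] * m[["mu3"]]
  gamma3 <- p[["gamma3"]] * m[["gamma3"]]
  delta3 <- p[["delta3"]] * m[["delta3"]]

  c(pathogen   = p[["alpha2"]] * M1 * P * eff - p[["gamma4"]] * N * P -
                 delta3 * P,
    neutrophil = p[["alpha1"]] * hill * cap - p[["gamma5"]] * N * IL6 -
                 p[["mu1"]] * N,
    monocyte   = p[["gamma5"]] * N * IL6 - p[["gamma2"]] * Mo - mu2 * Mo,
    M1         = p[["gamma2"]] * Mo - gamma3 * M1 * TGF - mu3 * M1,
    M2         = gamma3 * M1 * TGF - p[["mu4"]] * M2,
    IL6        = p[["beta"]] * N - p[["delta1"]] * IL6,
    TGFb       = p[["gamma1"]] * M1 * N - p[["delta2"]] * TGF)
}
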