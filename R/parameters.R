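#' Kinetic parameter set for the innate immune model
#'
#' Constructs and validates the full set of kinetic constants of the
#' seven-species sepsis model. All rates are per day; concentrations are in
#' arbitrary units (a.u.).
#'
#' @param alpha1 maximal neutrophil recruitment rate (1/day).
#' @param alpha2 M1--pathogen interaction rate (1/(a.u. day)). This is the only
#'   signed parameter: together with the effector function it carries the net
#'   direction of the M1--pathogen interaction below and above the activation
#'   threshold `theta_eff`.
#' @param beta IL-6 production rate per neutrophil (1/day).
#' @param gamma1 TGF-beta production rate from M1--neutrophil encounters.
#' @param gamma2 monocyte to M1 differentiation rate (1/day).
#' @param gamma3 TGF-beta-driven M1 to M2 polarization rate (1/(a.u. day)).
#' @param gamma4 neutrophil-mediated pathogen clearance rate (1/(a.u. day)).
#' @param gamma5 IL-6-mediated neutrophil-to-monocyte coupling rate
#'   (1/(a.u. day)).
#' @param delta1 IL-6 decay rate (1/day).
#' @param delta2 TGF-beta decay rate (1/day).
#' @param delta3 intrinsic pathogen removal rate (1/day).
#' @param mu1,mu2,mu3,mu4 decay rates of neutrophils, monocytes, M1 and M2
#'   macrophages (1/day).
#' @param Kn half-saturation pathogen level of the neutrophil recruitment Hill
#'   function (a.u.).
#' @param n_hill Hill coefficient of neutrophil recruitment (>= 1,
#'   dimensionless).
#' @param Cmax global myeloid carrying capacity (a.u. of cells).
#' @param theta_eff M1 activation threshold of the effector switch (a.u.).
#' @param kappa steepness of the effector switch (1/a.u.).
#'
#' @return An object of class `model_parameters`: a named numeric vector of the
#'   20 kinetic constants.
#' @seealso [nominal_parameters()], [derivatives()], [scale_parameters()]
#' @export
model_parameters <- function(alpha1, alpha2, beta, gamma1, gamma2, gamma3,
                             gamma4, gamma5, delta1, delta2, delta3,
                             mu1, mu2, mu3, mu4,
                             Kn, n_hill, Cmax, theta_eff, kappa) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, beta = beta,
         gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
         gamma4 = gamma4, gamma5 = gamma5,
         delta1 = delta1, delta2 = delta2, delta3 = delta3,
         mu1 = mu1, mu2 = mu2, mu3 = mu3, mu4 = mu4,
         Kn = Kn, n_hill = n_hill, Cmax = Cmax,
         theta_eff = theta_eff, kappa = kappa)
  validate_parameters(p)
}

#' @rdname model_parameters
#' @param x a named numeric vector or list carrying all 20 parameter names.
#' @export
as_model_parameters <- function(x) {
  x <- unlist(x)
  missing <- setdiff(parameter_names(), names(x))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(x), parameter_names())
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  validate_parameters(x[parameter_names()])
}

validate_parameters <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    stop("parameters must be finite numbers", call. = FALSE)
  # alpha2 is the only parameter allowed to carry either sign
  pos <- setdiff(parameter_names(), "alpha2")
  bad <- pos[p[pos] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (p[["n_hill"]] < 1)
    stop("n_hill must be >= 1", call. = FALSE)
  structure(as.double(p), names = parameter_names(),
            class = "model_parameters")
}

#' Parameter and species name sets
#'
#' `parameter_names()` returns the 20 kinetic constants in canonical order;
#' `scan_parameter_names()` the 19 varied in global sensitivity scans (all but
#' the Hill coefficient, which is held fixed so the scan perturbs rates and
#' thresholds on a common multiplicative scale); `species_names()` the seven
#' state variables; `actuated_rates()` the four rates a feedback controller may
#' target.
#' @return A character vector.
#' @export
parameter_names <- function() {
  c("alpha1", "alpha2", "beta", "gamma1", "gamma2", "gamma3", "gamma4",
    "gamma5", "delta1", "delta2", "delta3", "mu1", "mu2", "mu3", "mu4",
    "Kn", "n_hill", "Cmax", "theta_eff", "kappa")
}

#' @rdname parameter_names
#' @export
scan_parameter_names <- function() setdiff(parameter_names(), "n_hill")

#' @rdname parameter_names
#' @export
species_names <- function() {
  c("pathogen", "neutrophil", "monocyte", "M1", "M2", "IL6", "TGFb")
}

#' @rdname parameter_names
#' @export
actuated_rates <- function() c("mu3", "delta3", "mu2", "gamma3")

#' Bundled synthetic nominal parameter set
#'
#' The fitted parameter table of the original murine calibration is not
#' redistributable, so the package ships a synthetic stand-in: a parameter set
#' chosen once so that the nominal scenario (pathogen load 20 a.u. into a
#' resting system) resolves acutely within 8 days with the qualitative staging
#' of an innate response (early neutrophil burst, delayed monocyte/M1 wave,
#' late M2 accumulation, IL-6 excursions of order 0.2--2 a.u.). See the
#' methods vignette for the rationale behind each magnitude.
#'
#' @return A `model_parameters` object.
#' @export
nominal_parameters <- function() {
  path <- system.file("extdata", "synthetic_nominal.json", package = "sepsim",
                      mustWork = TRUE)
  read_parameters(path)
}

#' Read or write a parameter file
#'
#' Parameter files are flat key/value maps in JSON or YAML with keys named
#' exactly as the `model_parameters` fields.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_parameters()` returns a `model_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file extension: ", ext, call. = FALSE))
  raw <- raw[!startsWith(names(raw), "_")] # keys like "_comment" are ignored
  as_model_parameters(raw)
}

#' @rdname read_parameters
#' @param params a `model_parameters` object.
#' @export
write_parameters <- function(params, path) {
  params <- as_model_parameters(params)
  ext <- tolower(tools::file_ext(path))
  x <- as.list(unclass(params))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("unsupported parameter file extension: ", ext, call. = FALSE))
  invisible(path)
}

#' Rescale a parameter set by multiplicative factors
#'
#' @param base a `model_parameters` object.
#' @param factors named numeric vector of positive multipliers; names must be
#'   parameter names. Unnamed parameters are left untouched.
#' @return A `model_parameters` object.
#' @export
scale_parameters <- function(base, factors) {
  base <- as_model_parameters(base)
  if (length(factors)) {
    if (is.null(names(factors)) || !all(names(factors) %in% parameter_names()))
      stop("factors must be named by parameter", call. = FALSE)
    if (any(factors <= 0)) stop("scale factors must be positive", call. = FALSE)
    base[names(factors)] <- unclass(base)[names(factors)] * factors
  }
  validate_parameters(unclass(base))
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters> (rates per day, concentrations in a.u.)\n")
  print(structure(round(unclass(x), 6), names = names(x)))
  invisible(x)
}
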