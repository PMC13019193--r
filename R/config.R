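#' Default run configuration
#'
#' The defaults reproduce the reference campaign settings: initial pathogen
#' load 20 a.u. into a resting system, 8-day horizon, 1000-scenario cohort
#' scanned over [0.1, 10]x, the 7 x 4 x 6 = 168-cell controller grid, 100-set
#' +/-50% Latin-hypercube robustness over the six most impactful rates, the
#' 20-run x 30-combination secondary-infection campaign, and a controller at
#' (alpha = 10, n = 1, Kd = 0.2).
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    params = NULL,                       # path to a parameter file; NULL = bundled nominal
    seed = 1L,
    out_dir = "results",
    initial = list(pathogen = 20, neutrophil = 0, monocyte = 0, M1 = 0,
                   M2 = 0, IL6 = 0, TGFb = 0),
    horizon = 8,
    dt = 0.01,
    tolerances = list(rtol = 1e-6, atol = 1e-9),
    controller = list(name = "ck1", alpha = 10, n = 1, Kd = 0.2,
                      targets = NULL),
    cohort = list(n_samples = 1000, range = c(0.1, 10)),
    grid = list(alphas = c(0.1, 0.5, 1, 2, 5, 8, 10),
                ns = c(1, 2, 3, 4),
                Kds = c(0.2, 0.4, 0.6, 0.8, 1, 1.5)),
    robustness = list(varied_params = c("mu3", "mu4", "delta1", "gamma3",
                                        "beta", "delta3"),
                      n_sets = 100, rel_range = 0.5,
                      relative_to = "scenario"),
    secondary = list(healed_runs_n = 20, loads = c(10, 20, 30, 40, 50),
                     days = 2:7),
    fit = list(times = seq(0.5, 8, by = 0.5), noise_level = 0.1,
               free = c("mu3", "gamma3", "beta", "delta1", "gamma5"),
               n_starts = 5)
  ), class = "run_config")
}

# recursively overlay user values on defaults; unknown keys are an error
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key: ",
         paste(c(path, unknown[1]), collapse = "$"), call. = FALSE)
  for (nm in names(user)) {
    if (is.null(user[[nm]])) next # JSON null / absent: keep the default
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML scenario file, overlays it on [default_config()]
#' (missing keys keep their defaults; an empty file yields the full default
#' configuration) and validates it. Unknown keys raise an error naming the
#' offending key.
#'
#' @param path scenario file path (`.json`, `.yaml`, `.yml`), or `NULL` for
#'   pure defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
      json = if (file.size(path) > 0)
        jsonlite::read_json(path, simplifyVector = TRUE) else NULL,
      yaml = ,
      yml  = yaml::read_yaml(path),
      stop("unsupported config extension: ", ext, call. = FALSE))
  }
  cfg <- merge_config(unclass(default_config()), user)
  validate_config(structure(cfg, class = "run_config"))
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("unsupported config extension: ", ext, call. = FALSE))
  invisible(path)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(is.numeric(cfg$horizon) && cfg$horizon > 0, "horizon must be positive")
  chk(is.numeric(cfg$dt) && cfg$dt > 0, "dt must be positive")
  chk(all(names(cfg$initial) %in% species_names()),
      "initial must use species names")
  chk(all(unlist(cfg$initial) >= 0), "initial species must be nonnegative")
  chk(length(cfg$cohort$range) == 2 && all(cfg$cohort$range > 0) &&
        cfg$cohort$range[1] <= cfg$cohort$range[2],
      "cohort$range must be positive bounds [lo, hi]")
  chk(cfg$cohort$n_samples >= 1, "cohort$n_samples must be >= 1")
  chk(all(cfg$robustness$varied_params %in% parameter_names()),
      "robustness$varied_params must be parameter names")
  chk(cfg$robustness$rel_range >= 0 && cfg$robustness$rel_range < 1,
      "robustness$rel_range must be in [0, 1)")
  chk(cfg$robustness$relative_to %in% c("scenario", "nominal"),
      "robustness$relative_to must be 'scenario' or 'nominal'")
  chk(cfg$secondary$healed_runs_n >= 1, "secondary$healed_runs_n must be >= 1")
  chk(all(cfg$secondary$loads >= 0), "secondary$loads must be nonnegative")
  chk(is.numeric(cfg$seed), "seed must be an integer")
  # controller block must resolve
  config_controller(cfg)
  invisible(cfg)
}

# resolve the controller block into a controller_config (NULL if absent)
config_controller <- function(cfg) {
  cb <- cfg$controller
  if (is.null(cb)) return(NULL)
  if (!is.null(cb$name) && is.null(cb$targets))
    named_controller(cb$name, alpha = cb$alpha, n = cb$n, Kd = cb$Kd)
  else
    controller_config(cb$targets, alpha = cb$alpha, n = cb$n, Kd = cb$Kd,
                      name = cb$name)
}

config_params <- function(cfg) {
  if (is.null(cfg$params)) nominal_parameters() else read_parameters(cfg$params)
}

config_initial <- function(cfg) {
  s <- stats::setNames(rep(0, 7), species_names())
  s[names(cfg$initial)] <- unlist(cfg$initial)
  as_immune_state(s)
}
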