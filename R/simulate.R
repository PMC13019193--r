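#' Pulse perturbation event
#'
#' An instantaneous addition of `amount` a.u. to one species at a given time,
#' used e.g. to model a secondary microbial challenge.
#'
#' @param time event time in days (within the integration horizon).
#' @param species one of [species_names()].
#' @param amount added amount (a.u., > 0).
#' @return An object of class `pulse_event`.
#' @export
pulse_event <- function(time, species = "pathogen", amount) {
  if (!is.numeric(time) || length(time) != 1 || !is.finite(time) || time < 0)
    stop("event time must be a nonnegative scalar", call. = FALSE)
  if (!species %in% species_names())
    stop("unknown species: ", species, call. = FALSE)
  if (!is.numeric(amount) || length(amount) != 1 || !is.finite(amount) ||
      amount <= 0)
    stop("event amount must be positive", call. = FALSE)
  structure(list(time = time, species = species, amount = amount),
            class = "pulse_event")
}

#' Integrate the immune dynamics
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince 5(4)) integration of
#' [derivatives()] over `[0, horizon]`, with optional IL-6 feedback control
#' (the controller's rate multipliers are re-evaluated from the instantaneous
#' IL-6 level at every derivative evaluation) and optional pulse events, each
#' of which splits the integration and adds its amount to the named species.
#' The trajectory is sampled on a uniform grid; tiny negative excursions are
#' projected to 0 both inside the right-hand side and before storage.
#'
#' @param params a `model_parameters` set.
#' @param initial an `immune_state` at time 0.
#' @param horizon final time in days (> 0).
#' @param controller optional `controller_config`; `NULL` for the uncontrolled
#'   system.
#' @param events optional list of [pulse_event()]s with times in
#'   `[0, horizon]`.
#' @param dt output grid resolution in days (default 0.01).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param sample_times optional extra sample times in `[0, horizon]` merged
#'   into the output grid (the solver stops exactly at them; used e.g. to read
#'   predictions at observation times without interpolation).
#' @return An object of class `sepsim_trajectory`: list with `times` (uniform
#'   grid from 0), `states` (matrix, one row per time, columns
#'   [species_names()]), `params`, `controller`, `events`, `n_steps`. At a
#'   grid time coinciding with an event, the stored state is post-pulse.
#' @export
integrate_model <- function(params, initial, horizon = 8,
                            controller = NULL, events = NULL,
                            dt = 0.01, rtol = 1e-6, atol = 1e-9,
                            sample_times = NULL) {
  p <- as_model_parameters(params)
  y0 <- as_immune_state(initial)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0)
    stop("horizon must be a positive scalar (days)", call. = FALSE)
  if (dt <= 0 || dt > horizon) stop("invalid dt", call. = FALSE)

  if (!is.null(events)) {
    if (inherits(events, "pulse_event")) events <- list(events)
    ok <- vapply(events, inherits, logical(1), what = "pulse_event")
    if (!all(ok)) stop("events must be pulse_event objects", call. = FALSE)
    ev_t <- vapply(events, `[[`, numeric(1), "time")
    if (any(ev_t < 0 | ev_t > horizon))
      stop("event time outside [0, horizon]", call. = FALSE)
    o <- order(ev_t)
    events <- events[o]
    ev_t <- ev_t[o]
    ev_sp <- vapply(events, `[[`, character(1), "species")
    ev_am <- vapply(events, `[[`, numeric(1), "amount")
  } else {
    events <- list()
    ev_t <- numeric(0); ev_sp <- character(0); ev_am <- numeric(0)
  }

  times <- seq(0, horizon, by = dt)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  if (!is.null(sample_times)) {
    if (any(sample_times < 0 | sample_times > horizon))
      stop("sample_times outside [0, horizon]", call. = FALSE)
    times <- sort(unique(c(times, sample_times)))
  }

  has_ctrl <- !is.null(controller)
  if (has_ctrl && !inherits(controller, "controller_config"))
    stop("controller must be a controller_config or NULL", call. = FALSE)
  tmask <- if (has_ctrl) actuated_rates() %in% controller$targets
           else rep(FALSE, 4)

  res <- tryCatch(
    .integrate_core(unclass(y0), unclass(p), times,
                    ev_t, match(ev_sp, species_names()) - 1L, ev_am,
                    has_ctrl,
                    if (has_ctrl) controller$alpha else 0,
                    if (has_ctrl) controller$n else 1,
                    if (has_ctrl) controller$Kd else 1,
                    tmask, rtol, atol, 5e6),
    error = function(e)
      stop("integration failed: ", conditionMessage(e), call. = FALSE))

  states <- res$states
  colnames(states) <- species_names()
  structure(list(times = times, states = states, params = p,
                 controller = controller, events = events,
                 n_steps = res$n_steps),
            class = "sepsim_trajectory")
}

#' Extract a species' time course or the state at a time
#'
#' @param traj a `sepsim_trajectory`.
#' @param species one of [species_names()].
#' @param time a time on the trajectory grid (linear interpolation between
#'   grid points).
#' @return `species_course()` a numeric vector over the grid; `state_at()` an
#'   `immune_state`.
#' @export
species_course <- function(traj, species) {
  stopifnot(inherits(traj, "sepsim_trajectory"))
  if (!species %in% species_names())
    stop("unknown species: ", species, call. = FALSE)
  traj$states[, species]
}

#' @rdname species_course
#' @export
state_at <- function(traj, time) {
  stopifnot(inherits(traj, "sepsim_trajectory"))
  if (time < traj$times[1] || time > traj$times[length(traj$times)])
    stop("time outside trajectory range", call. = FALSE)
  vals <- vapply(species_names(), function(sp)
    stats::approx(traj$times, traj$states[, sp], xout = time)$y, numeric(1))
  as_immune_state(vals)
}

#' Acute/septic outcome classification
#'
#' Reads the pathogen level at day 8 and labels the run `"acute"` when at
#' least 90% of the initial load has been cleared by then (boundary
#' inclusive: with an initial load of 20 a.u., a day-8 level of exactly
#' 2 a.u. is acute), `"septic"` otherwise.
#'
#' @param traj a `sepsim_trajectory` covering t = 8 days.
#' @param initial_pathogen initial load (a.u., > 0); defaults to the
#'   trajectory's own pathogen level at t = 0.
#' @param eval_day evaluation time (days, default 8).
#' @return A `simulation_outcome`: list with `pathogen_at_day8`,
#'   `clearance_fraction` and `label`.
#' @export
classify <- function(traj, initial_pathogen = NULL, eval_day = 8) {
  stopifnot(inherits(traj, "sepsim_trajectory"))
  if (traj$times[length(traj$times)] < eval_day)
    stop("trajectory horizon shorter than the evaluation day (",
         eval_day, ")", call. = FALSE)
  if (is.null(initial_pathogen)) initial_pathogen <- traj$states[1, "pathogen"]
  if (initial_pathogen <= 0)
    stop("initial pathogen load must be positive", call. = FALSE)
  p8 <- state_at(traj, eval_day)[["pathogen"]]
  cf <- 1 - p8 / initial_pathogen
  structure(list(pathogen_at_day8 = p8,
                 clearance_fraction = cf,
                 label = if (cf >= 0.9) "acute" else "septic"),
            class = "simulation_outcome")
}

#' @export
print.simulation_outcome <- function(x, ...) {
  cat(sprintf("<simulation_outcome> %s: pathogen(day 8) = %.4g, clearance = %.1f%%\n",
              x$label, x$pathogen_at_day8, 100 * x$clearance_fraction))
  invisible(x)
}

#' @export
print.sepsim_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<sepsim_trajectory> %d samples over [0, %g] days (%d steps)\n",
              n, x$times[n], as.integer(x$n_steps)))
  cat("  controller:",
      if (is.null(x$controller)) "none"
      else paste0(if (!is.null(x$controller$name)) x$controller$name else "custom",
                  " -> ", paste(x$controller$targets, collapse = "+")), "\n")
  if (length(x$events))
    cat("  events:", length(x$events), "pulse(s)\n")
  final <- x$states[n, ]
  cat("  final state:", paste(sprintf("%s=%.3g", names(final), final),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a trajectory
#'
#' The time course goes to a tidy long-format CSV (`time`, `species`,
#' `value`, full double precision) and the run metadata (parameters,
#' controller, events, outcome) to a JSON sidecar `<path>.json`.
#'
#' @param traj a `sepsim_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` the path, invisibly; `read_trajectory()` a
#'   list with `data` (the long data frame) and `meta` (the sidecar list).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sepsim_trajectory"))
  long <- data.frame(
    time = rep(traj$times, times = length(species_names())),
    species = rep(species_names(), each = length(traj$times)),
    value = as.vector(traj$states))
  write_csv_full(long, path)
  meta <- list(
    params = as.list(unclass(traj$params)),
    controller = if (is.null(traj$controller)) NULL else
      list(name = traj$controller$name, targets = traj$controller$targets,
           alpha = traj$controller$alpha, n = traj$controller$n,
           Kd = traj$controller$Kd),
    events = lapply(traj$events, function(e)
      list(time = e$time, species = e$species, amount = e$amount)),
    outcome = if (traj$times[length(traj$times)] >= 8)
      unclass(classify(traj)) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(data = data, meta = meta)
}

# full-precision CSV writer shared by all artifact outputs
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
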