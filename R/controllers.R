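#' IL-6 feedback controller configuration
#'
#' A controller senses the instantaneous IL-6 level and multiplies each of its
#' target rates by the shared Hill term
#' `1 + alpha * IL6^n / (Kd^n + IL6^n)`, so every actuated rate is scaled
#' between 1x (no IL-6) and `(1 + alpha)`x (saturating IL-6).
#'
#' @param targets non-empty character subset of [actuated_rates()]:
#'   `mu3` (M1 clearance), `delta3` (pathogen removal), `mu2` (monocyte
#'   removal), `gamma3` (M1-to-M2 polarization).
#' @param alpha controller strength (gain, >= 0, dimensionless).
#' @param n cooperativity of the Hill activation (>= 1).
#' @param Kd activation threshold on the IL-6 axis (> 0, a.u.).
#' @param name optional label (set automatically by [named_controller()]).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(targets, alpha = 10, n = 1, Kd = 0.2,
                              name = NULL) {
  if (!length(targets) || !all(targets %in% actuated_rates()))
    stop("targets must be a non-empty subset of: ",
         paste(actuated_rates(), collapse = ", "), call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha < 0)
    stop("alpha must be a nonnegative scalar", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1)
    stop("n must be >= 1", call. = FALSE)
  if (!is.numeric(Kd) || length(Kd) != 1 || !is.finite(Kd) || Kd <= 0)
    stop("Kd must be a positive scalar", call. = FALSE)
  structure(list(targets = unique(targets), alpha = alpha, n = n, Kd = Kd,
                 name = name),
            class = "controller_config")
}

#' Named controller laws
#'
#' The eight standard IL-6 feedback laws, keyed by the rate set they actuate:
#' `ck1` ({mu3}: accelerate M1 clearance), `ck2` ({delta3}: boost innate
#' pathogen removal), `ck3` ({mu2}: deplete monocytes), `ck4` ({gamma3}:
#' promote M2 polarization), `dual1` ({mu3, delta3}), `dual2` ({mu3, gamma3}),
#' `dual3` ({gamma3, delta3}) and `triple` ({mu3, delta3, gamma3}). All share
#' one Hill term applied elementwise to each target rate.
#'
#' @param name one of `"ck1"`, `"ck2"`, `"ck3"`, `"ck4"`, `"dual1"`,
#'   `"dual2"`, `"dual3"`, `"triple"` (case-insensitive).
#' @inheritParams controller_config
#' @return A `controller_config`.
#' @export
named_controller <- function(name, alpha = 10, n = 1, Kd = 0.2) {
  key <- tolower(name)
  targets <- controller_target_table()[[key]]
  if (is.null(targets))
    stop("unknown controller name: ", name, " (expected one of ",
         paste(names(controller_target_table()), collapse = ", "), ")",
         call. = FALSE)
  controller_config(targets, alpha = alpha, n = n, Kd = Kd, name = key)
}

#' @rdname named_controller
#' @return `controller_target_table()` returns the full name-to-targets map.
#' @export
controller_target_table <- function() {
  list(ck1    = "mu3",
       ck2    = "delta3",
       ck3    = "mu2",
       ck4    = "gamma3",
       dual1  = c("mu3", "delta3"),
       dual2  = c("mu3", "gamma3"),
       dual3  = c("gamma3", "delta3"),
       triple = c("mu3", "delta3", "gamma3"))
}

#' Controller actuation multiplier
#'
#' The shared Hill-type multiplier applied to every target rate:
#' `1 + alpha * IL6^n / (Kd^n + IL6^n)`.
#'
#' @param IL6 IL-6 level(s), a.u., >= 0 (vectorized).
#' @param config a `controller_config`.
#' @return Multiplier(s) in `[1, 1 + alpha]`.
#' @export
control_multiplier <- function(IL6, config) {
  stopifnot(inherits(config, "controller_config"))
  if (anyNA(IL6) || any(!is.finite(IL6)) || any(IL6 < 0))
    stop("IL6 must be finite and nonnegative", call. = FALSE)
  hn <- IL6^config$n
  m <- ifelse(IL6 > 0, 1 + config$alpha * hn / (config$Kd^config$n + hn), 1)
  as.double(m)
}

#' Per-rate multipliers at a given state
#'
#' Maps a controller law onto the four actuation points of [derivatives()]:
#' each target rate gets [control_multiplier()] of the state's IL-6 level,
#' every other actuated rate stays at 1.
#'
#' @param state an `immune_state`.
#' @param config a `controller_config`.
#' @return Named numeric vector over [actuated_rates()].
#' @export
multipliers_for_state <- function(state, config) {
  s <- as_immune_state(state)
  m <- stats::setNames(rep(1, length(actuated_rates())), actuated_rates())
  m[config$targets] <- control_multiplier(s[["IL6"]], config)
  m
}

#' @export
print.controller_config <- function(x, ...) {
  cat("<controller_config>",
      if (!is.null(x$name)) paste0("[", x$name, "]") else "", "\n")
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  cat(sprintf("  alpha = %g, n = %g, Kd = %g a.u. IL-6\n", x$alpha, x$n, x$Kd))
  invisible(x)
}
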