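#' Time-course dataset of observed immune cell counts
#'
#' Observed neutrophil, M1 and M2 counts at common observation times, the
#' calibration target of [fit_parameters()].
#'
#' @param times observation times (days), nonnegative and strictly
#'   increasing, at least 3 points.
#' @param neutrophil,M1,M2 observed counts (a.u.), one value per time.
#' @param weights optional per-point weights (recycled across species), > 0.
#' @return An object of class `timecourse_dataset`.
#' @export
timecourse_dataset <- function(times, neutrophil, M1, M2, weights = NULL) {
  if (length(times) < 3 || any(times < 0) || any(diff(times) <= 0))
    stop("times must be >= 0, strictly increasing, with at least 3 points",
         call. = FALSE)
  obs <- cbind(neutrophil = neutrophil, M1 = M1, M2 = M2)
  if (nrow(obs) != length(times))
    stop("each species needs one observation per time", call. = FALSE)
  if (anyNA(obs) || any(!is.finite(obs)))
    stop("observations must be finite", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != length(times) || any(weights <= 0))
      stop("weights must be positive, one per time point", call. = FALSE)
  }
  structure(list(times = as.double(times), observed = obs, weights = weights),
            class = "timecourse_dataset")
}

#' @rdname timecourse_dataset
#' @param path CSV with columns `time`, `species` (neutrophil/M1/M2), `value`
#'   and optionally `weight` (long format, as written by
#'   [write_timecourse()]).
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "species", "value")
  if (!all(need %in% names(df)))
    stop("time-course CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  wide <- lapply(c("neutrophil", "M1", "M2"), function(sp) {
    sub <- df[df$species == sp, ]
    sub[order(sub$time), ]
  })
  times <- wide[[1]]$time
  for (w in wide)
    if (!identical(w$time, times))
      stop("all species must share the same observation times", call. = FALSE)
  weights <- if ("weight" %in% names(df)) wide[[1]]$weight else NULL
  timecourse_dataset(times, wide[[1]]$value, wide[[2]]$value, wide[[3]]$value,
                     weights = weights)
}

#' @rdname timecourse_dataset
#' @param dataset a `timecourse_dataset`.
#' @export
write_timecourse <- function(dataset, path) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  sp <- colnames(dataset$observed)
  df <- data.frame(
    time = rep(dataset$times, times = length(sp)),
    species = rep(sp, each = length(dataset$times)),
    value = as.vector(dataset$observed))
  if (!is.null(dataset$weights))
    df$weight <- rep(dataset$weights, times = length(sp))
  write_csv_full(df, path)
  invisible(path)
}

#' Model predictions at observation times
#'
#' Integrates the model and returns the predicted neutrophil, M1 and M2
#' levels exactly at the requested times (the solver stops at each, so no
#' interpolation is involved).
#'
#' @param params a `model_parameters` set.
#' @param initial an `immune_state` at t = 0.
#' @param times observation times (days, >= 0).
#' @param rtol,atol integration tolerances.
#' @return Matrix with one row per time and columns neutrophil, M1, M2.
#' @export
simulate_observables <- function(params, initial, times,
                                 rtol = 1e-6, atol = 1e-9) {
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  horizon <- max(times, 1e-3)
  traj <- integrate_model(params, initial, horizon = horizon,
                          dt = min(0.01, horizon), rtol = rtol, atol = atol,
                          sample_times = times)
  idx <- match(times, traj$times)
  out <- traj$states[idx, c("neutrophil", "M1", "M2"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# normalized weighted residual sum of squares (per-species max normalization)
fit_rss <- function(params, dataset, initial, rtol, atol) {
  pred <- simulate_observables(params, initial, dataset$times,
                               rtol = rtol, atol = atol)
  scale <- pmax(apply(abs(dataset$observed), 2, max), .Machine$double.eps)
  res <- sweep(dataset$observed - pred, 2, scale, "/")
  w <- if (is.null(dataset$weights)) 1 else dataset$weights
  sum(w * res^2)
}

#' Least-squares calibration of the kinetic parameters
#'
#' Minimizes the summed squared residual over the neutrophil, M1 and M2 time
#' courses jointly, each species normalized by its maximum observed value so
#' that species of different magnitude contribute comparably. A bounded
#' quasi-Newton optimizer (L-BFGS-B on the log of each free parameter's
#' magnitude; signs are fixed by the initial guess) is run from the supplied
#' guess plus optional random multistarts drawn log-uniformly within the
#' bounds.
#'
#' @param dataset a `timecourse_dataset`.
#' @param initial_guess starting `model_parameters` (must lie within bounds).
#' @param bounds optional list with named numeric vectors `lower` and `upper`
#'   for a subset of parameters; defaults to a factor of 100 around the guess
#'   (sign-preserving).
#' @param fixed character vector of parameter names held at their guess
#'   value; everything else is free.
#' @param initial `immune_state` at t = 0 for the fitted experiment (default:
#'   resting system with a 20 a.u. pathogen load).
#' @param n_starts total optimizer starts (1 = the guess only; additional
#'   starts are random within bounds).
#' @param seed integer seed for the multistarts.
#' @param rtol,atol integration tolerances used during fitting.
#' @return A `fit_result`: list with `params` (best fit), `rss`,
#'   `per_species_rss`, `converged`, `bounds`, `fixed`, `trace` (best-so-far
#'   RSS after each start), `n_starts`, `seed`.
#' @export
fit_parameters <- function(dataset, initial_guess, bounds = NULL,
                           fixed = character(),
                           initial = immune_state(pathogen = 20),
                           n_starts = 1, seed = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  guess <- as_model_parameters(initial_guess)
  if (!all(fixed %in% parameter_names()))
    stop("fixed must name model parameters", call. = FALSE)
  free <- setdiff(parameter_names(), fixed)
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)

  lower <- unclass(guess); upper <- unclass(guess)
  pos <- unclass(guess) > 0
  lower[pos] <- unclass(guess)[pos] / 100
  upper[pos] <- unclass(guess)[pos] * 100
  lower[!pos] <- unclass(guess)[!pos] * 100
  upper[!pos] <- unclass(guess)[!pos] / 100
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  if (any(lower > unclass(guess) | unclass(guess) > upper))
    stop("initial guess outside bounds", call. = FALSE)
  if (any(sign(lower[free]) != sign(upper[free])))
    stop("bounds of a free parameter must not straddle zero", call. = FALSE)
  # n_hill >= 1 must survive the fit
  lower["n_hill"] <- max(lower["n_hill"], 1)

  sgn <- sign(unclass(guess)[free])
  zlo <- log(pmin(abs(lower[free]), abs(upper[free])))
  zhi <- log(pmax(abs(lower[free]), abs(upper[free])))

  objective <- function(z) {
    p <- unclass(guess)
    p[free] <- sgn * exp(z)
    val <- tryCatch(
      fit_rss(validate_parameters(p), dataset, initial, rtol, atol),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  starts <- list(log(abs(unclass(guess)[free])))
  if (n_starts > 1) {
    extra <- with_seed(if (is.null(seed)) NULL else child_seed(seed, 5), {
      lapply(seq_len(n_starts - 1), function(i)
        stats::runif(length(free), zlo, zhi))
    })
    starts <- c(starts, extra)
  }

  best <- NULL
  trace <- numeric(0)
  for (z0 in starts) {
    fit <- tryCatch(
      stats::optim(z0, objective, method = "L-BFGS-B",
                   lower = zlo, upper = zhi,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    trace <- c(trace, if (is.null(best)) NA_real_ else best$value)
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10)
    stop("fit failed: no finite-residual solution found from any start",
         call. = FALSE)

  p <- unclass(guess)
  p[free] <- sgn * exp(best$par)
  fitted <- validate_parameters(p)

  pred <- simulate_observables(fitted, initial, dataset$times,
                               rtol = rtol, atol = atol)
  scale <- pmax(apply(abs(dataset$observed), 2, max), .Machine$double.eps)
  res2 <- sweep(dataset$observed - pred, 2, scale, "/")^2
  w <- if (is.null(dataset$weights)) 1 else dataset$weights
  per_species <- colSums(w * res2)

  structure(list(params = fitted, rss = best$value,
                 per_species_rss = per_species,
                 converged = best$convergence == 0,
                 bounds = list(lower = lower, upper = upper),
                 fixed = fixed, trace = trace,
                 n_starts = length(starts), seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> RSS = %.6g (%s, %d start%s)\n", x$rss,
              if (x$converged) "converged" else "not converged",
              x$n_starts, if (x$n_starts > 1) "s" else ""))
  cat("  fixed:", if (length(x$fixed)) paste(x$fixed, collapse = ", ")
                  else "none", "\n")
  invisible(x)
}

#' Write a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(params = as.list(unclass(fit$params)), rss = fit$rss,
         per_species_rss = as.list(fit$per_species_rss),
         converged = fit$converged,
         bounds = lapply(fit$bounds, as.list),
         fixed = fit$fixed, trace = fit$trace,
         n_starts = fit$n_starts, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' One-at-a-time local sensitivity ranking
#'
#' Perturbs each parameter by a relative amount about `params` and measures a
#' scalar trajectory functional (default: pathogen level at day 8) by central
#' difference. The reported sensitivity is normalized,
#' `(dM/M) / (dtheta/theta)`, so it is invariant to rescaling of the metric;
#' if the baseline metric is 0 the absolute form `dM / (dtheta/theta)` is
#' used with a warning.
#'
#' @param params a `model_parameters` set.
#' @param perturbation relative step (default 0.1, i.e. +/-10%).
#' @param metric function(trajectory) -> scalar; default pathogen at day 8.
#' @param initial `immune_state` at t = 0 (default resting + 20 a.u. load).
#' @param horizon integration horizon (days).
#' @param which_params parameters to rank (default all 20).
#' @return Data frame (param, sensitivity, rank), ordered by decreasing
#'   absolute sensitivity.
#' @export
local_sensitivity_ranking <- function(params, perturbation = 0.1,
                                      metric = NULL,
                                      initial = immune_state(pathogen = 20),
                                      horizon = 8,
                                      which_params = parameter_names()) {
  p0 <- as_model_parameters(params)
  if (perturbation <= 0 || perturbation >= 1)
    stop("perturbation must be in (0, 1)", call. = FALSE)
  if (is.null(metric))
    metric <- function(traj) state_at(traj, 8)[["pathogen"]]
  evalm <- function(p) metric(integrate_model(p, initial, horizon = horizon))

  m0 <- evalm(p0)
  absolute <- FALSE
  if (m0 == 0) {
    warning("baseline metric is 0; reporting absolute sensitivities",
            call. = FALSE)
    absolute <- TRUE
  }
  sens <- vapply(which_params, function(nm) {
    up <- unclass(p0); up[nm] <- up[nm] * (1 + perturbation)
    dn <- unclass(p0); dn[nm] <- dn[nm] * (1 - perturbation)
    # n_hill may not drop below 1 under perturbation
    if (nm == "n_hill" && dn[nm] < 1) dn[nm] <- 1
    dm <- evalm(validate_parameters(up)) - evalm(validate_parameters(dn))
    rel_step <- (up[nm] - dn[nm]) / unclass(p0)[nm]
    if (absolute) dm / rel_step else (dm / m0) / rel_step
  }, numeric(1))
  out <- data.frame(param = which_params, sensitivity = sens,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$sensitivity)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Synthetic noisy time course
#'
#' Generates a calibration fixture from the model itself:
#' [simulate_observables()] plus multiplicative log-normal noise whose
#' coefficient of variation equals `noise_level` (sdlog =
#' sqrt(log(1 + noise_level^2))). A stand-in for unavailable experimental
#' cell-count data.
#'
#' @param params generating `model_parameters`.
#' @param initial `immune_state` at t = 0.
#' @param times observation times (days).
#' @param noise_level target coefficient of variation (>= 0; 0 returns the
#'   exact model output).
#' @param seed integer seed.
#' @return A `timecourse_dataset`.
#' @export
generate_synthetic_timecourse <- function(params, initial, times,
                                          noise_level = 0.1, seed = NULL) {
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  pred <- simulate_observables(params, initial, times)
  if (noise_level > 0) {
    sdlog <- sqrt(log(1 + noise_level^2))
    noise <- with_seed(seed,
      matrix(exp(stats::rnorm(length(pred), 0, sdlog)), nrow = nrow(pred)))
    pred <- pred * noise
  }
  timecourse_dataset(times, pred[, "neutrophil"], pred[, "M1"], pred[, "M2"])
}
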