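#' Latin hypercube sample on the unit cube
#'
#' Stratified sampling: for each of the `k` dimensions independently, the `n`
#' draws occupy the `n` equal-probability strata `[(i-1)/n, i/n)` exactly once,
#' in random order.
#'
#' @param n number of samples (rows).
#' @param k number of dimensions (columns).
#' @param seed optional integer seed.
#' @return An `n` x `k` matrix of values in (0, 1).
#' @export
lhs_sample <- function(n, k, seed = NULL) {
  stopifnot(n >= 1, k >= 1)
  with_seed(seed, {
    m <- matrix(0, n, k)
    for (j in seq_len(k))
      m[, j] <- (sample.int(n) - 1 + stats::runif(n)) / n
    m
  })
}

#' Sample a virtual cohort by uniform parameter scaling
#'
#' Draws `n_samples` parameter sets by scaling each of the 19 varied
#' parameters ([scan_parameter_names()]; the Hill coefficient is held fixed)
#' by independent uniform factors on `[range[1], range[2]]`.
#'
#' @param base nominal `model_parameters`.
#' @param n_samples cohort size (default 1000).
#' @param range positive factor range, default `c(0.1, 10)`.
#' @param seed integer seed for reproducibility.
#' @return A list of scenarios, each a `cohort_scenario`: list with `id`,
#'   `factors` (named scale factors) and `params` (the realized set).
#' @export
sample_cohort <- function(base, n_samples = 1000, range = c(0.1, 10),
                          seed = NULL) {
  base <- as_model_parameters(base)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (length(range) != 2 || any(range <= 0) || range[1] > range[2])
    stop("range must be positive bounds [lo, hi]", call. = FALSE)
  vary <- scan_parameter_names()
  facs <- with_seed(seed, matrix(stats::runif(n_samples * length(vary),
                                              range[1], range[2]),
                                 nrow = n_samples,
                                 dimnames = list(NULL, vary)))
  lapply(seq_len(n_samples), function(i) {
    f <- facs[i, ]
    structure(list(id = i, factors = f,
                   params = scale_parameters(base, f)),
              class = "cohort_scenario")
  })
}

#' Run a cohort of scenarios and classify outcomes
#'
#' Integrates each scenario from a resting system hit by an initial pathogen
#' load, classifies the day-8 outcome, and summarizes the acute fraction.
#' Scenarios whose integration fails are recorded and excluded from the
#' success-rate denominator with a warning (solver failures are not biology).
#'
#' @param scenarios list of `cohort_scenario` objects (or bare
#'   `model_parameters`, which are wrapped).
#' @param initial_pathogen initial load, a.u. (default 20).
#' @param controller optional `controller_config` applied to every run.
#' @param initial optional full `immune_state` at t = 0 overriding the default
#'   resting state (all species 0 except the pathogen load).
#' @param horizon integration horizon (days, >= 8).
#' @param dt output resolution (days).
#' @return A `campaign_result`: list with `outcomes` (data frame: id, ok,
#'   pathogen_at_day8, clearance_fraction, label), `success_rate` (acute
#'   fraction among successful integrations), `n_failed`, and the input
#'   `scenarios`.
#' @export
run_cohort <- function(scenarios, initial_pathogen = 20, controller = NULL,
                       initial = NULL, horizon = 8, dt = 0.01) {
  if (!length(scenarios)) stop("scenarios must be non-empty", call. = FALSE)
  scenarios <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    if (inherits(sc, "cohort_scenario")) sc
    else structure(list(id = i, factors = NULL,
                        params = as_model_parameters(sc)),
                   class = "cohort_scenario")
  })
  if (is.null(initial)) {
    initial <- immune_state(pathogen = initial_pathogen)
  } else {
    initial <- as_immune_state(initial)
    initial["pathogen"] <- initial_pathogen
  }

  rows <- lapply(scenarios, function(sc) {
    out <- tryCatch({
      traj <- integrate_model(sc$params, initial, horizon = horizon,
                              controller = controller, dt = dt)
      oc <- classify(traj, initial_pathogen = initial_pathogen)
      data.frame(id = sc$id, ok = TRUE,
                 pathogen_at_day8 = oc$pathogen_at_day8,
                 clearance_fraction = oc$clearance_fraction,
                 label = oc$label, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = sc$id, ok = FALSE, pathogen_at_day8 = NA_real_,
                 clearance_fraction = NA_real_, label = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out
  })
  outcomes <- do.call(rbind, rows)
  n_failed <- sum(!outcomes$ok)
  if (n_failed > 0)
    warning(n_failed, " scenario(s) failed to integrate and were excluded",
            call. = FALSE)
  ok <- outcomes$ok
  structure(list(outcomes = outcomes,
                 success_rate = mean(outcomes$label[ok] == "acute"),
                 n_failed = n_failed,
                 scenarios = scenarios),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  n <- nrow(x$outcomes)
  cat(sprintf("<campaign_result> %d scenario(s), %d failed\n", n, x$n_failed))
  cat(sprintf("  acute (success) fraction: %.1f%%\n", 100 * x$success_rate))
  invisible(x)
}

#' Extract scenario subsets by outcome label
#'
#' @param result a `campaign_result` from [run_cohort()].
#' @param label `"septic"` or `"acute"`.
#' @return The list of `cohort_scenario`s with that outcome.
#' @export
scenario_subset <- function(result, label = "septic") {
  stopifnot(inherits(result, "campaign_result"))
  keep <- result$outcomes$ok & result$outcomes$label == label
  result$scenarios[keep]
}

#' Controller hyperparameter grid optimization
#'
#' Evaluates a named controller over the full (alpha, n, Kd) grid on a set of
#' septic scenarios, scoring each cell by its success rate (fraction of
#' scenarios reverted to acute healing by day 8). The default grids span
#' 7 x 4 x 6 = 168 combinations. The argmax cell is returned with
#' deterministic tie-breaking: smaller alpha, then smaller Kd, then smaller n
#' (prefer the least aggressive equally-performing controller).
#'
#' @param septic_scenarios non-empty list of `cohort_scenario`s.
#' @param controller_name a [named_controller()] name (default `"ck1"`).
#' @param alphas,ns,Kds grid axes.
#' @param initial_pathogen initial load (a.u.).
#' @param dt output resolution (days).
#' @return List with `grid` (data frame: alpha, n, Kd, n_success, n_total,
#'   success_rate) and `best` (one-row data frame at the argmax).
#' @export
optimize_grid <- function(septic_scenarios, controller_name = "ck1",
                          alphas = c(0.1, 0.5, 1, 2, 5, 8, 10),
                          ns = c(1, 2, 3, 4),
                          Kds = c(0.2, 0.4, 0.6, 0.8, 1, 1.5),
                          initial_pathogen = 20, dt = 0.01) {
  if (!length(septic_scenarios))
    stop("septic scenario set must be non-empty", call. = FALSE)
  if (!length(alphas) || !length(ns) || !length(Kds))
    stop("grids must be non-empty", call. = FALSE)
  cells <- expand.grid(alpha = alphas, n = ns, Kd = Kds,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    ctrl <- named_controller(controller_name, alpha = cells$alpha[i],
                             n = cells$n[i], Kd = cells$Kd[i])
    r <- suppressWarnings(
      run_cohort(septic_scenarios, initial_pathogen = initial_pathogen,
                 controller = ctrl, dt = dt))
    ok <- r$outcomes$ok
    data.frame(n_success = sum(r$outcomes$label[ok] == "acute"),
               n_total = sum(ok))
  })
  grid <- cbind(cells, do.call(rbind, res))
  grid$success_rate <- grid$n_success / grid$n_total
  o <- order(-grid$success_rate, grid$alpha, grid$Kd, grid$n)
  list(grid = grid, best = grid[o[1], , drop = FALSE])
}

#' Latin-hypercube robustness analysis of a controller
#'
#' For each septic scenario, perturbs the six most impactful parameters by
#' Latin-hypercube factors within `1 +/- rel_range` (per stratum, one draw
#' each) and re-runs the controlled simulation `n_sets` times, yielding a
#' per-scenario success rate, the pooled rate over all runs, and success
#' rates stratified by each parameter's perturbation factor: low
#' (0.5--0.8x), nominal (0.8--1.2x), high (1.2--2.0x).
#'
#' @param septic_scenarios non-empty list of `cohort_scenario`s.
#' @param controller a `controller_config`.
#' @param varied_params parameters to perturb (default the six rate constants
#'   `mu3, mu4, delta1, gamma3, beta, delta3`).
#' @param n_sets LHS sets per scenario (default 100).
#' @param rel_range relative half-width of the perturbation (default 0.5,
#'   i.e. +/-50%); must be < 1.
#' @param seed integer seed.
#' @param relative_to `"scenario"` (default: perturb each scenario's own
#'   values) or `"nominal"` (perturb a common base set).
#' @param base nominal `model_parameters`, required for
#'   `relative_to = "nominal"`.
#' @param initial_pathogen initial load (a.u.).
#' @param dt output resolution (days).
#' @return List with `per_scenario` (data frame: id, n_ok, n_success,
#'   success_rate), `pooled` (total successes / total runs), `stratified`
#'   (data frame: param, bin, n, success_rate), and the factor matrices in
#'   `factors` (one `n_sets` x length(varied_params) matrix per scenario).
#' @export
robustness_lhs <- function(septic_scenarios, controller,
                           varied_params = c("mu3", "mu4", "delta1",
                                             "gamma3", "beta", "delta3"),
                           n_sets = 100, rel_range = 0.5, seed = NULL,
                           relative_to = c("scenario", "nominal"),
                           base = NULL, initial_pathogen = 20, dt = 0.01) {
  if (!length(septic_scenarios))
    stop("septic scenario set must be non-empty", call. = FALSE)
  if (!all(varied_params %in% parameter_names()))
    stop("varied_params must be model parameter names", call. = FALSE)
  if (rel_range < 0 || rel_range >= 1)
    stop("rel_range must be in [0, 1) (factors must stay positive)",
         call. = FALSE)
  relative_to <- match.arg(relative_to)
  if (relative_to == "nominal" && is.null(base))
    stop("base parameters required when relative_to = 'nominal'",
         call. = FALSE)

  k <- length(varied_params)
  bins <- c(low = 0.5, nominal = 0.8, high = 1.2, upper = 2.0)

  per <- vector("list", length(septic_scenarios))
  fac_list <- vector("list", length(septic_scenarios))
  strat_rows <- list()

  for (s in seq_along(septic_scenarios)) {
    sc <- septic_scenarios[[s]]
    facs <- 1 - rel_range +
      2 * rel_range * lhs_sample(n_sets, k,
                                 seed = if (is.null(seed)) NULL
                                        else child_seed(seed, s))
    colnames(facs) <- varied_params
    fac_list[[s]] <- facs

    ref <- if (relative_to == "scenario") sc$params
           else as_model_parameters(base)
    success <- rep(NA, n_sets)
    for (i in seq_len(n_sets)) {
      p <- unclass(ref)
      p[varied_params] <- p[varied_params] * facs[i, ]
      success[i] <- tryCatch({
        traj <- integrate_model(validate_parameters(p),
                                immune_state(pathogen = initial_pathogen),
                                horizon = 8, controller = controller, dt = dt)
        classify(traj, initial_pathogen)$label == "acute"
      }, error = function(e) NA)
    }
    ok <- !is.na(success)
    per[[s]] <- data.frame(id = sc$id, n_ok = sum(ok),
                           n_success = sum(success[ok]),
                           success_rate = mean(success[ok]))
    strat_rows[[s]] <- data.frame(
      success = rep(success, k),
      param = rep(varied_params, each = n_sets),
      factor = as.vector(facs))
  }

  per_scenario <- do.call(rbind, per)
  pooled <- sum(per_scenario$n_success) / sum(per_scenario$n_ok)

  strat <- do.call(rbind, strat_rows)
  strat <- strat[!is.na(strat$success), ]
  if (any(strat$factor < bins[1] | strat$factor > bins[4]))
    stop("perturbation factor outside the stratification bins [0.5, 2.0]",
         call. = FALSE)
  strat$bin <- cut(strat$factor, breaks = bins, include.lowest = TRUE,
                   right = FALSE, labels = c("low", "nominal", "high"))
  agg <- stats::aggregate(success ~ param + bin, data = strat,
                          FUN = function(x) c(n = length(x), rate = mean(x)))
  stratified <- data.frame(param = agg$param, bin = agg$bin,
                           n = agg$success[, "n"],
                           success_rate = agg$success[, "rate"])

  list(per_scenario = per_scenario, pooled = pooled, stratified = stratified,
       factors = fac_list)
}

#' Secondary-infection stress test
#'
#' Randomly selects `healed_runs_n` controller-rescued scenarios and, for each
#' of the 5 x 6 = 30 combinations of secondary load (percent of the initial
#' pathogen load) and injection day, re-simulates the controlled run with the
#' corresponding pathogen pulse. Success is >= 90% clearance of the *initial*
#' load by day 8; among successes, the clearance time is the first grid time
#' after the pulse at which the pathogen level falls to <= 10% of the initial
#' load, measured from the pulse time.
#'
#' @param healed_scenarios list of `cohort_scenario`s rescued by the
#'   controller (e.g. `scenario_subset(result, "acute")` from a controlled
#'   [run_cohort()]).
#' @param controller the `controller_config` that rescued them.
#' @param healed_runs_n number of healed runs to sample (default 20).
#' @param loads secondary loads in percent of the initial load (default
#'   10--50%).
#' @param days injection days (default 2--7).
#' @param initial_pathogen initial load (a.u.).
#' @param seed integer seed for the healed-run selection.
#' @param dt output resolution (days).
#' @return List with `per_run` (data frame: scenario id, load_pct, day,
#'   success, clearance_time), `success_count`, `n_total`, `success_rate`,
#'   and `clearance_table` (data frame: load_pct, day, n_success,
#'   mean_clearance_time over successes).
#' @export
secondary_infection_campaign <- function(healed_scenarios, controller,
                                         healed_runs_n = 20,
                                         loads = c(10, 20, 30, 40, 50),
                                         days = 2:7,
                                         initial_pathogen = 20, seed = NULL,
                                         dt = 0.01) {
  if (length(healed_scenarios) < healed_runs_n)
    stop("need at least ", healed_runs_n, " healed scenarios, got ",
         length(healed_scenarios), call. = FALSE)
  picked <- with_seed(seed,
    sample(seq_along(healed_scenarios), healed_runs_n))
  threshold <- 0.1 * initial_pathogen

  rows <- list()
  for (idx in picked) {
    sc <- healed_scenarios[[idx]]
    for (load in loads) for (day in days) {
      amount <- load / 100 * initial_pathogen
      ev <- if (amount > 0) list(pulse_event(day, "pathogen", amount))
      traj <- integrate_model(sc$params,
                              immune_state(pathogen = initial_pathogen),
                              horizon = 8, controller = controller,
                              events = ev, dt = dt)
      oc <- classify(traj, initial_pathogen)
      ct <- NA_real_
      if (oc$label == "acute") {
        path <- species_course(traj, "pathogen")
        after <- traj$times > day
        hit <- which(after & path <= threshold)
        if (length(hit)) ct <- traj$times[hit[1]] - day
      }
      rows[[length(rows) + 1]] <-
        data.frame(id = sc$id, load_pct = load, day = day,
                   success = oc$label == "acute", clearance_time = ct)
    }
  }
  per_run <- do.call(rbind, rows)
  tab <- expand.grid(load_pct = loads, day = days, KEEP.OUT.ATTRS = FALSE)
  tab$n_success <- NA_integer_
  tab$mean_clearance_time <- NA_real_
  for (i in seq_len(nrow(tab))) {
    sel <- per_run$load_pct == tab$load_pct[i] & per_run$day == tab$day[i]
    tab$n_success[i] <- sum(per_run$success[sel])
    cts <- per_run$clearance_time[sel & per_run$success]
    if (length(cts)) tab$mean_clearance_time[i] <- mean(cts, na.rm = TRUE)
  }
  list(per_run = per_run,
       success_count = sum(per_run$success),
       n_total = nrow(per_run),
       success_rate = mean(per_run$success),
       clearance_table = tab)
}
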