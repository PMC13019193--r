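obs_times <- c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8)

test_that("simulate_observables evaluates the model at the requested times", {
  z <- simulate_observables(nominal, immune_state(), times = 0)
  expect_equal(unname(z), matrix(0, 1, 3), ignore_attr = TRUE)
  a <- simulate_observables(nominal, invasion, obs_times)
  b <- simulate_observables(nominal, invasion, obs_times)
  expect_identical(a, b)
  expect_equal(dim(a), c(length(obs_times), 3))
  expect_equal(colnames(a), c("neutrophil", "M1", "M2"))
  expect_error(simulate_observables(nominal, invasion, c(-1, 2)),
               "nonnegative")
})

test_that("observable predictions agree with dense trajectory output", {
  # oracle: a finely sampled trajectory at tight tolerance, interpolated
  pred <- simulate_observables(nominal, invasion, obs_times,
                               rtol = 1e-10, atol = 1e-12)
  dense <- integrate_model(nominal, invasion, horizon = 8, dt = 1e-3,
                           rtol = 1e-10, atol = 1e-12)
  for (k in seq_along(obs_times)) {
    ref <- state_at(dense, obs_times[k])
    for (sp in c("neutrophil", "M1", "M2"))
      expect_lt(abs(pred[k, sp] - ref[[sp]]) / max(abs(ref[[sp]]), 1e-8),
                1e-8)
  }
})

test_that("synthetic time courses are exact at zero noise, seeded, and carry the stated CV", {
  ds0 <- generate_synthetic_timecourse(nominal, invasion, obs_times,
                                       noise_level = 0, seed = 5)
  expect_equal(unname(ds0$observed),
               unname(simulate_observables(nominal, invasion, obs_times)))
  d1 <- generate_synthetic_timecourse(nominal, invasion, obs_times, 0.1, 17)
  d2 <- generate_synthetic_timecourse(nominal, invasion, obs_times, 0.1, 17)
  expect_identical(d1$observed, d2$observed)
  expect_false(identical(
    d1$observed,
    generate_synthetic_timecourse(nominal, invasion, obs_times, 0.1, 18)$observed))
  # Monte Carlo CV check: pool the multiplicative residuals of many draws
  dense_times <- seq(0.5, 8, length.out = 120)
  pred <- simulate_observables(nominal, invasion, dense_times)
  ratios <- unlist(lapply(1:30, function(s) {
    ds <- generate_synthetic_timecourse(nominal, invasion, dense_times,
                                        noise_level = 0.1, seed = 1000 + s)
    ds$observed / pred
  }))
  cv <- stats::sd(ratios) / mean(ratios)
  expect_lt(abs(cv - 0.1) / 0.1, 0.02)
})

test_that("time-course datasets validate and round-trip through CSV", {
  expect_error(timecourse_dataset(c(1, 2), 1:2, 1:2, 1:2), "at least 3")
  expect_error(timecourse_dataset(c(1, 2, 2), 1:3, 1:3, 1:3), "increasing")
  ds <- generate_synthetic_timecourse(nominal, invasion, obs_times, 0.05, 9)
  f <- tempfile(fileext = ".csv")
  write_timecourse(ds, f)
  back <- read_timecourse(f)
  expect_identical(back$times, ds$times)
  expect_identical(back$observed, ds$observed)
  unlink(f)
})

test_that("fitting a noiseless dataset from the truth is self-consistent", {
  free <- c("mu3", "gamma3", "beta", "delta1", "gamma5")
  ds <- generate_synthetic_timecourse(nominal, invasion, obs_times, 0)
  fit <- fit_parameters(ds, nominal, fixed = setdiff(parameter_names(), free))
  expect_lt(fit$rss, 1e-10)
  expect_true(all(abs(unclass(fit$params) / unclass(nominal) - 1) < 1e-6))
})

test_that("the fit recovers generating parameters from a perturbed start", {
  # noiseless data, five free parameters, guess off by x2 / x0.5
  free <- c("mu3", "gamma3", "beta", "delta1", "gamma5")
  ds <- generate_synthetic_timecourse(nominal, invasion, obs_times, 0)
  guess <- scale_parameters(nominal, c(mu3 = 2, gamma3 = 0.5, beta = 2,
                                       delta1 = 0.5, gamma5 = 2))
  fit <- fit_parameters(ds, guess, fixed = setdiff(parameter_names(), free))
  expect_true(fit$converged)
  rel <- abs(unclass(fit$params)[free] / unclass(nominal)[free] - 1)
  expect_lt(max(rel), 0.01)
  # best-so-far residual bookkeeping is non-increasing
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("with noisy data the multistart fit is at least as good as the truth", {
  free <- c("mu3", "beta", "delta1")
  ds <- generate_synthetic_timecourse(nominal, invasion, obs_times,
                                      noise_level = 0.05, seed = 31)
  fit <- fit_parameters(ds, nominal,
                        fixed = setdiff(parameter_names(), free),
                        n_starts = 3, seed = 31)
  rss_truth <- sepsim:::fit_rss(nominal, ds, invasion, 1e-8, 1e-10)
  expect_lte(fit$rss, rss_truth + 1e-12)
})

test_that("local sensitivity ranking has the stated structural properties", {
  # a pathogen-free resting system with cells: pathogen terms are inert
  st <- immune_state(pathogen = 0, neutrophil = 10, monocyte = 2, M1 = 3,
                     IL6 = 1, TGFb = 0.5)
  m2_metric <- function(traj) state_at(traj, 8)[["M2"]]
  rk <- local_sensitivity_ranking(nominal, metric = m2_metric, initial = st)
  s <- stats::setNames(rk$sensitivity, rk$param)
  expect_equal(unname(s[c("gamma4", "delta3", "alpha2", "alpha1", "Kn",
                          "theta_eff", "kappa")]), rep(0, 7))
  expect_gt(abs(s[["gamma3"]]), 0)
  # normalization: invariant to rescaling the metric
  rk1000 <- local_sensitivity_ranking(
    nominal, metric = function(tr) 1000 * m2_metric(tr), initial = st)
  expect_equal(rk1000$sensitivity, rk$sensitivity, tolerance = 1e-9)
  # zero baseline metric switches to absolute sensitivities with a warning
  expect_warning(
    local_sensitivity_ranking(nominal, initial = immune_state(neutrophil = 1)),
    "absolute")
})

test_that("the top-six ranking is stable under halving the perturbation", {
  rk_a <- local_sensitivity_ranking(nominal, perturbation = 0.1)
  rk_b <- local_sensitivity_ranking(nominal, perturbation = 0.05)
  expect_setequal(rk_a$param[1:6], rk_b$param[1:6])
})
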