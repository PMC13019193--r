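# Campaign tests run on deliberately scaled-down cohorts (tens of scenarios,
# coarser output grids) to keep the suite fast; the machinery is identical to
# the full-size campaigns.

test_that("cohort sampling is uniform-in-factor, seeded and 19-dimensional", {
  scen <- sample_cohort(nominal, n_samples = 40, range = c(0.1, 10), seed = 7)
  expect_length(scen, 40)
  facs <- t(vapply(scen, `[[`, numeric(19), "factors"))
  expect_equal(colnames(facs), scan_parameter_names())
  expect_true(all(facs >= 0.1 & facs <= 10))
  # the Hill coefficient is never varied
  for (sc in scen)
    expect_identical(sc$params[["n_hill"]], nominal[["n_hill"]])
  # determinism
  scen2 <- sample_cohort(nominal, 40, c(0.1, 10), seed = 7)
  expect_identical(facs, t(vapply(scen2, `[[`, numeric(19), "factors")))
  # degenerate range reproduces the base set
  for (sc in sample_cohort(nominal, 3, c(1, 1), seed = 1))
    expect_equal(unclass(sc$params), unclass(nominal))
  expect_error(sample_cohort(nominal, 10, c(-1, 2)), "positive")
})

test_that("run_cohort classifies, summarizes and exposes the septic subset", {
  # the bundled nominal scenario resolves acutely, the septic fixture does not
  res <- run_cohort(list(nominal, septic_params), dt = 0.02)
  expect_equal(res$outcomes$label, c("acute", "septic"))
  expect_equal(res$success_rate, 0.5)
  expect_equal(res$n_failed, 0)
  sep <- scenario_subset(res, "septic")
  expect_length(sep, 1)
  expect_equal(unclass(sep[[1]]$params), unclass(septic_params))
  # absent controller and zero-gain controller agree label-by-label
  scen <- sample_cohort(nominal, 12, seed = 11)
  r0 <- run_cohort(scen, dt = 0.02)
  rz <- run_cohort(scen, dt = 0.02,
                   controller = controller_config("mu3", alpha = 0))
  expect_identical(r0$outcomes$label, rz$outcomes$label)
})

test_that("the default optimization grid has exactly 168 cells", {
  # grid construction only; success rates evaluated on a single scenario
  opt <- optimize_grid(list(structure(list(id = 1, factors = NULL,
                                           params = septic_params),
                                      class = "cohort_scenario")),
                       alphas = c(0.1, 0.5, 1, 2, 5, 8, 10),
                       ns = 1:4, Kds = c(0.2, 0.4, 0.6, 0.8, 1, 1.5),
                       dt = 0.1)
  expect_equal(nrow(opt$grid), 168)
  expect_equal(nrow(unique(opt$grid[c("alpha", "n", "Kd")])), 168)
})

test_that("grid argmax honors the deterministic tie-break", {
  sc <- list(structure(list(id = 1, factors = NULL, params = septic_params),
                       class = "cohort_scenario"))
  # single cell: best is that cell
  opt1 <- optimize_grid(sc, alphas = 5, ns = 2, Kds = 0.4, dt = 0.05)
  expect_equal(opt1$best[c("alpha", "n", "Kd")],
               data.frame(alpha = 5, n = 2, Kd = 0.4),
               ignore_attr = TRUE)
  # this fixture is rescued by every gain >= 0.5: all cells tie at rate 1,
  # so the least aggressive controller must win (alpha, then Kd, then n)
  opt <- optimize_grid(sc, alphas = c(0.5, 1, 2), ns = c(1, 2),
                       Kds = c(0.2, 0.4), dt = 0.05)
  expect_true(all(opt$grid$success_rate == 1))
  expect_equal(opt$best$alpha, 0.5)
  expect_equal(opt$best$Kd, 0.2)
  expect_equal(opt$best$n, 1)
  expect_error(optimize_grid(list()), "non-empty")
})

test_that("latin hypercube stratification is exact in every dimension", {
  for (n in c(7, 100)) {
    m <- lhs_sample(n, 6, seed = 99)
    expect_true(all(m > 0 & m < 1))
    for (j in 1:6) {
      strata <- floor(m[, j] * n)      # stratum index of each draw
      expect_setequal(strata, 0:(n - 1))  # exactly one draw per stratum
    }
  }
  expect_identical(lhs_sample(50, 6, seed = 1), lhs_sample(50, 6, seed = 1))
})

test_that("robustness analysis counts, stratifies and degenerates correctly", {
  sep <- list(structure(list(id = 1, factors = NULL, params = septic_params),
                        class = "cohort_scenario"),
              structure(list(id = 2, factors = NULL,
                             params = scale_parameters(septic_params,
                                                       c(beta = 1.1))),
                        class = "cohort_scenario"))
  ck1 <- named_controller("ck1")
  rob <- robustness_lhs(sep, ck1, n_sets = 10, rel_range = 0.5, seed = 3,
                        dt = 0.05)
  expect_equal(nrow(rob$per_scenario), 2)
  expect_equal(rob$per_scenario$n_ok, c(10, 10))      # 2 x 10 runs executed
  expect_length(rob$factors, 2)
  expect_equal(dim(rob$factors[[1]]), c(10, 6))
  expect_true(all(rob$factors[[1]] >= 0.5 & rob$factors[[1]] <= 1.5))
  # pooled rate is total successes over total runs
  expect_equal(rob$pooled, sum(rob$per_scenario$n_success) / 20)
  # stratified summary uses the stated bins
  expect_setequal(levels(rob$stratified$bin), c("low", "nominal", "high"))
  expect_setequal(unique(as.character(rob$stratified$param)),
                  c("mu3", "mu4", "delta1", "gamma3", "beta", "delta3"))
  # within each parameter the bin counts add up to all runs
  for (pm in unique(rob$stratified$param))
    expect_equal(sum(rob$stratified$n[rob$stratified$param == pm]), 20)
  # degenerate perturbation: every run identical, rate 0 or 1 per scenario
  rob0 <- robustness_lhs(sep[1], ck1, n_sets = 5, rel_range = 0, seed = 3,
                         dt = 0.05)
  expect_true(rob0$per_scenario$success_rate %in% c(0, 1))
  expect_error(robustness_lhs(sep, ck1, rel_range = 1), "rel_range")
})

test_that("secondary-infection campaign runs all load x day combinations", {
  ck1 <- named_controller("ck1")
  healed <- lapply(1:3, function(i)
    structure(list(id = i, factors = NULL, params = septic_params),
              class = "cohort_scenario"))
  sec <- secondary_infection_campaign(healed, ck1, healed_runs_n = 2,
                                      loads = c(10, 30, 50), days = c(2, 5),
                                      seed = 13, dt = 0.05)
  expect_equal(sec$n_total, 2 * 3 * 2)
  expect_equal(nrow(sec$clearance_table), 6)
  expect_equal(sec$success_count, sum(sec$per_run$success))
  # clearance times, where defined, are measured from the pulse, within day 8
  ok <- !is.na(sec$per_run$clearance_time)
  expect_true(all(sec$per_run$clearance_time[ok] >= 0))
  expect_true(all(sec$per_run$clearance_time[ok] <=
                    8 - sec$per_run$day[ok] + 1e-9))
  # zero-magnitude pulse reproduces the unperturbed healed run
  sec0 <- secondary_infection_campaign(healed[1], ck1, healed_runs_n = 1,
                                       loads = 0, days = 4, seed = 1,
                                       dt = 0.05)
  base <- classify(integrate_model(septic_params, invasion, 8,
                                   controller = ck1, dt = 0.05), 20)
  expect_equal(sec0$per_run$success, base$label == "acute")
  expect_error(secondary_infection_campaign(healed, ck1, healed_runs_n = 5),
               "at least 5")
  # selection is seeded
  s1 <- secondary_infection_campaign(healed, ck1, 2, loads = 10, days = 2,
                                     seed = 21, dt = 0.1)
  s2 <- secondary_infection_campaign(healed, ck1, 2, loads = 10, days = 2,
                                     seed = 21, dt = 0.1)
  expect_identical(s1$per_run, s2$per_run)
})
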