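mk_stats <- function(t, S, n, comp) {
  structure(list(
    summary = data.frame(timepoint_days = t, n_clones = 100L, S = S,
                         mean_n_persisting = n, mean_m = NA_real_),
    composition = comp, cdf = list(), bins = ssc_bins()),
    class = "ssc_stats")
}

test_that("residuals reproduce forced arithmetic and additivity", {
  comp_o <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("A_s", "A_pr")))
  comp_s <- matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("A_s", "A_pr")))
  obs <- mk_stats(6, 0.5, 4, comp_o)
  sim <- mk_stats(6, 0.4, 3, comp_s)

  expect_equal(unclass(compute_residuals(obs, obs, 6))[c("R1", "R2", "R3")],
               list(R1 = 0, R2 = 0, R3 = 0))

  res <- compute_residuals(sim, obs, 6)
  expect_equal(res$R1, 0.02)
  expect_equal(res$R2, 0.0625)
  expect_equal(res$R3, 0.01)

  # identical discrepancies at two timepoints double every residual
  obs2 <- mk_stats(c(6, 10), c(0.5, 0.5), c(4, 4),
                   comp_o[c(1, 1), , drop = FALSE])
  sim2 <- mk_stats(c(6, 10), c(0.4, 0.4), c(3, 3),
                   comp_s[c(1, 1), , drop = FALSE])
  res2 <- compute_residuals(sim2, obs2, c(6, 10))
  expect_equal(res2$R1, 0.04)
  expect_equal(res2$R2, 0.125)
  expect_equal(res2$R3, 0.02)

  expect_error(compute_residuals(sim, obs, c(6, 14)), "missing fit timepoint")

  # composition alignment is invariant to bin-column order
  sim_perm <- mk_stats(6, 0.4, 3, comp_s[, c(2, 1), drop = FALSE])
  expect_equal(compute_residuals(sim_perm, obs, 6)$R1, 0.02)
})

test_that("the composite cost is the sum of log residuals with a floor", {
  expect_equal(cost_value(list(R1 = 1, R2 = 1, R3 = 1)), 0)
  expect_equal(cost_value(list(R1 = 0.02, R2 = 0.0625, R3 = 0.01)),
               log(0.02) + log(0.0625) + log(0.01))
  expect_equal(cost_value(list(R1 = 0, R2 = 1, R3 = 1)), log(1e-12))
  # scaling every residual by c shifts C by 3 ln c
  r <- list(R1 = 0.3, R2 = 0.07, R3 = 0.011)
  r4 <- lapply(r, `*`, 4)
  expect_equal(cost_value(r4), cost_value(r) + 3 * log(4))
  expect_error(cost_value(list(R1 = -1, R2 = 1, R3 = 1)), ">= 0")
})

test_that("residuals are invariant to clone relabeling", {
  ds <- generate_dataset(study_design(harvest_times = c(2, 6),
                                      clones_per_time = 60, seed = 20))
  tab <- ds$table
  shuffled <- tab[sample(nrow(tab)), ]
  shuffled$clone_id <- paste0("relabel", seq_len(nrow(tab)))
  a <- ensemble_statistics(tab)
  b <- ensemble_statistics(shuffled)
  res <- compute_residuals(a, b, c(2, 6))
  expect_equal(res$R1 + res$R2 + res$R3, 0)
})

test_that("CMA-ES minimizes a smooth bowl deterministically within bounds", {
  sphere <- function(x, gen, idx) sum((x - c(1, -2))^2)
  o1 <- cma_es(sphere, x0 = c(0, 0), sigma0 = 1, lower = -5, upper = 5,
               popsize = 8, generations = 40, seed = 21)
  o2 <- cma_es(sphere, x0 = c(0, 0), sigma0 = 1, lower = -5, upper = 5,
               popsize = 8, generations = 40, seed = 21)
  expect_equal(o1$par, c(1, -2), tolerance = 1e-3)
  expect_identical(o1$par, o2$par)
  expect_identical(o1$history, o2$history)

  # bound-constrained optimum lands on the boundary
  o3 <- cma_es(sphere, x0 = c(0, 0), sigma0 = 1, lower = -5, upper = c(0.5, 5),
               popsize = 8, generations = 40, seed = 22)
  expect_equal(o3$par[1], 0.5, tolerance = 1e-6)
  expect_gt(o3$n_clipped, 0)

  # an objective that reseeds the global RNG does not derail the search
  noisy <- function(x, gen, idx) { set.seed(1); sum(x^2) }
  o4 <- cma_es(noisy, x0 = c(2, 2), sigma0 = 1, popsize = 8,
               generations = 30, seed = 23)
  expect_lt(o4$value, 1e-4)
})

test_that("small fits are reproducible end to end", {
  truth <- ssc_params()
  ds <- generate_dataset(study_design(harvest_times = c(2, 6, 10),
                                      clones_per_time = 60, seed = 24))
  cfg <- fit_config(fit_times = c(2, 6, 10), n_realizations = 80,
                    popsize = 4, generations = 3, seed = 25)
  f1 <- fit_parameters(ds$table, truth, config = cfg)
  f2 <- fit_parameters(ds$table, truth, config = cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$cost, f2$cost)
  expect_identical(f1$history, f2$history)
  expect_s3_class(f1, "ssc_fit")
  expect_true(is.finite(f1$cost))
  expect_true(all(unlist(f1$par[c("eta_frag", "gamma_loss")]) > 0))
  expect_error(fit_parameters(ds$table, truth,
                              config = fit_config(fit_times = c(2, 6, 14))),
               "missing fit timepoint")
})

test_that("sensitivity grids use exact symmetric offsets and flag invalid cells", {
  ds <- generate_dataset(study_design(harvest_times = c(2, 6),
                                      clones_per_time = 40, seed = 26))
  ref <- update_params(ssc_params(), t0_loss_end = 2.5)
  sc <- sensitivity_scan(ds$table, ref,
                         offsets = seq(-0.75, 0.75, length.out = 3),
                         pairs = list(c("gamma_loss", "t0_loss_end")),
                         n_realizations = 50, fit_times = c(2, 6), seed = 27)
  expect_equal(sc$offsets, c(-0.75, 0, 0.75))
  g <- sc$grids$gamma_loss_x_t0_loss_end
  # t0 * 0.25 = 0.625 < t_start: the whole low-t0 column is invalid
  expect_true(all(is.na(g[, 1])))
  expect_true(all(is.finite(g[, 2:3])))
  expect_equal(sc$contour_step, log(2))
})

test_that("repeated cost evaluations shrink in spread with more realizations", {
  ds <- generate_dataset(study_design(harvest_times = c(2, 6),
                                      clones_per_time = 80, seed = 28))
  obs_stats <- ensemble_statistics(ds$table)
  sd_ <- empirical_seed_distribution(ds$table, 2)
  p <- update_params(ssc_params(), mu_prog = 0, m_mode = "deterministic")
  evals <- function(n_real) vapply(1:10, function(i)
    sscdyn:::evaluate_cost(p, obs_stats, sd_, c(2, 6), n_real,
                           sim_seed = 1000 + i, bins = ssc_bins(),
                           epsilon_floor = 1e-12)$cost, numeric(1))
  expect_lt(sd(evals(400)), sd(evals(100)))
})
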