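test_that("simulation is reproducible and validates record times", {
  p <- ssc_params()
  s <- clone_state(1)
  t1 <- simulate_clone(s, p, record_times = c(2, 6, 10), seed = 99)
  t2 <- simulate_clone(s, p, record_times = c(2, 6, 10), seed = 99)
  expect_identical(t1$states, t2$states)

  e1 <- simulate_ensemble(default_seed_distribution(), p, 50,
                          record_times = c(2, 6, 10), seed = 4)
  e2 <- simulate_ensemble(default_seed_distribution(), p, 50,
                          record_times = c(2, 6, 10), seed = 4)
  expect_identical(e1$n_total, e2$n_total)
  expect_identical(e1$lengths, e2$lengths)

  expect_error(simulate_clone(s, p, record_times = c(1, 6)), "t_start")
  expect_error(simulate_clone(s, p, record_times = c(6, 6)), "increasing")
  expect_error(simulate_ensemble(default_seed_distribution(), p, 0,
                                 record_times = 6, seed = 1), ">= 1")
})

test_that("frozen dynamics leave every trajectory constant", {
  p <- ssc_params(lambda_div = 0, eta_frag = 0, gamma_loss = 0, mu_prog = 0)
  ens <- simulate_ensemble(default_seed_distribution(), p, 40,
                           record_times = c(2, 10, 30), seed = 5)
  expect_true(all(ens$n_total == ens$n_total[, 1]))
  expect_true(all(ens$m == 0))
})

test_that("pure-death survival follows the exponential closed form", {
  gamma <- 0.4
  times <- c(2, 4, 6)
  n <- 3000
  ens <- simulate_ensemble(single_cell_seeding(), pure_death_params(gamma),
                           n, record_times = times, seed = 6)
  S <- colMeans(ens$n_total >= 1)
  theory <- exp(-gamma * (times - 2))
  se <- sqrt(theory * (1 - theory) / n)
  expect_true(all(abs(S - theory) <= 3 * se + 1e-12))
})

test_that("incomplete division doubles syncytia and grows the mean exponentially", {
  lambda <- 0.35
  times <- c(2, 6, 10)
  n <- 3000
  ens <- simulate_ensemble(single_cell_seeding(), pure_division_params(lambda),
                           n, record_times = times, seed = 7)
  # with division only, a clone is always a single unit of length 2^d
  lens <- unlist(ens$lengths)
  expect_true(all(lens %in% 2^(0:20)))
  expect_true(all(vapply(ens$lengths,
                         function(l) all(lengths(l) == 1L), logical(1))))
  for (j in seq_along(times)) {
    mean_n <- mean(ens$n_total[, j])
    sem <- sd(ens$n_total[, j]) / sqrt(n)
    expect_lt(abs(mean_n - exp(lambda * (times[j] - 2))), 3 * sem + 1e-12)
  }
})

test_that("fragmentation alone conserves total nuclei on an empty lattice", {
  p <- ssc_params(lambda_div = 0, eta_frag = 0.6, gamma_loss = 0, mu_prog = 0)
  ens <- simulate_ensemble(
    seed_distribution(list(list(lengths = 8L, m_prog = 0)), 1),
    p, 500, record_times = c(2, 6, 12, 20), seed = 8)
  # the clone stays sparse enough that no self-collision differentiates nuclei
  # in most realizations; total nuclei n + m is conserved in all of them
  expect_true(all(ens$n_total + round(ens$m) == 8))
})

test_that("site exclusivity caps the unit count at the lattice size", {
  p <- ssc_params(lambda_div = 1, eta_frag = 1.5, gamma_loss = 0,
                  mu_prog = 0, r_range = 1, lattice_sites = 5)
  ens <- simulate_ensemble(single_cell_seeding(), p, 100,
                           record_times = c(2, 6, 12), seed = 9)
  units <- vapply(ens$lengths, function(l) max(lengths(l)), integer(1))
  expect_true(all(units <= 5))
})

test_that("stochastic and deterministic progenitor modes agree in the mean", {
  mu <- 0.4
  times <- c(2, 6, 10)
  n <- 4000
  p_sto <- ssc_params(lambda_div = 0, eta_frag = 0, gamma_loss = 0,
                      mu_prog = mu, m_mode = "stochastic")
  p_det <- update_params(p_sto, m_mode = "deterministic")
  seeding <- single_cell_seeding(m0 = 2)
  sto <- simulate_ensemble(seeding, p_sto, n, times, seed = 10)
  det <- simulate_ensemble(seeding, p_det, n, times, seed = 10)
  theory <- 2 * exp(mu * (times - 2))
  expect_equal(colMeans(det$m), theory, tolerance = 1e-10)
  sem <- apply(sto$m, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(sto$m) - theory) <= 3 * sem + 1e-12))
})

test_that("clones can be lost only during the loss phase", {
  p <- ssc_params()  # gamma > 0, t0 = 8.1
  ens <- simulate_ensemble(default_seed_distribution(), p, 400,
                           record_times = c(2, 5, 8.1, 9, 14, 20, 28),
                           seed = 11)
  alive <- ens$n_total >= 1
  # survival is non-increasing in time for every realization
  for (j in 2:ncol(alive)) expect_true(all(alive[, j] <= alive[, j - 1]))
  # after t0 the set of surviving clones never changes
  post <- which(ens$record_times > p$t0_loss_end)
  for (j in post[-1]) expect_identical(alive[, j], alive[, post[1]])
})
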