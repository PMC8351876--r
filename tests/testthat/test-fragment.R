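test_that("fragment_lengths conserves nuclei and honors forced bridge states", {
  expect_error(fragment_lengths(1), "length_k")
  expect_identical(fragment_lengths(2, breaks = FALSE), 2L)
  expect_identical(fragment_lengths(2, breaks = TRUE), c(1L, 1L))
  expect_identical(fragment_lengths(4, breaks = c(TRUE, FALSE, TRUE)),
                   c(1L, 2L, 1L))
  set.seed(10)
  for (k in 2:8) {
    for (rep in 1:200) expect_equal(sum(fragment_lengths(k)), k)
  }
})

test_that("each bridge breaks independently with probability 1/2", {
  set.seed(42)
  n_draws <- 1e4
  split2 <- mean(vapply(seq_len(n_draws),
                        function(i) length(fragment_lengths(2)) == 2L,
                        logical(1)))
  # 3 binomial s.e. around 1/2
  expect_lt(abs(split2 - 0.5), 3 * sqrt(0.25 / n_draws))
})

test_that("fragment-count distribution matches exhaustive bridge enumeration", {
  set.seed(7)
  n_draws <- 1e4
  k <- 4
  counts <- vapply(seq_len(n_draws),
                   function(i) length(fragment_lengths(k)), integer(1))
  expected <- enumerate_fragment_counts(k)   # (1,3,3,1)/8 over 1..4 fragments
  expect_equal(expected[4], 1 / 8)           # all three bridges break
  expect_equal(sum(seq_len(k) * expected), 2.5)  # mean fragment count
  obs <- tabulate(counts, nbins = k)
  chi <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(chi$p.value, 0.01)
  expect_lt(abs(mean(counts) - 2.5), 3 * sd(counts) / sqrt(n_draws))
})

test_that("event propensities follow the per-unit and per-bridge rates", {
  p <- ssc_params(lambda_div = 0.5, eta_frag = 0.2, gamma_loss = 0.4,
                  t0_loss_end = 8, mu_prog = 0.3)
  s <- clone_state(lengths = c(1, 2, 4), m_prog = 3, time = 4)
  tab <- event_propensities(s, p)
  agg <- tapply(tab$rate, tab$event, sum)
  expect_equal(unname(agg[["division"]]), 3 * 0.5)
  expect_equal(unname(agg[["fragmentation"]]), (0 + 1 + 3) * 0.2)
  expect_equal(unname(agg[["death"]]), 3 * 0.4)
  expect_equal(unname(agg[["progenitor_birth"]]), 3 * 0.3)
  expect_equal(attr(tab, "total"), 1.5 + 0.8 + 1.2 + 0.9)

  # after the loss phase the death channel is off
  s_late <- clone_state(lengths = c(1, 2, 4), m_prog = 3, time = 9)
  tab_late <- event_propensities(s_late, p)
  expect_false("death" %in% tab_late$event)

  # extinct clone is absorbing
  s_empty <- clone_state(lengths = integer(0), m_prog = 0, time = 4)
  expect_equal(attr(event_propensities(s_empty, p), "total"), 0)
})

test_that("fragmentation events conserve nuclei and site exclusivity", {
  p <- ssc_params(r_range = 1, lattice_sites = 101)
  # isolated pair on an empty lattice, forced both-fragments split
  s <- clone_state(lengths = 2L, m_prog = 0, time = 3, sites = 50L)
  set.seed(1)
  out <- apply_fragmentation(s, 1, p, breaks = TRUE)
  expect_identical(sort(out$lengths), c(1L, 1L))
  expect_equal(length(unique(out$sites)), 2L)
  expect_equal(out$m_prog, 0)

  # a displaced fragment may land on a neighbor, which then differentiates
  set.seed(2)
  evicted <- 0L
  for (i in 1:400) {
    s2 <- clone_state(lengths = c(2L, 1L), m_prog = 0, time = 3,
                      sites = c(50L, 51L))
    out2 <- apply_fragmentation(s2, 1, p, breaks = TRUE)
    total <- sum(out2$lengths) + out2$m_prog
    expect_equal(total, 3)                      # nuclei bookkeeping
    expect_false(anyDuplicated(out2$sites) > 0) # one unit per site
    if (out2$m_prog == 1) {
      evicted <- evicted + 1L
      expect_equal(length(out2$lengths), 2L)  # unit count unchanged
    }
  }
  # the displaced single lands on site 51 half the time
  expect_gt(evicted, 120)
  expect_lt(evicted, 280)
})

test_that("fragmentation on an empty neighborhood conserves total nuclei", {
  # a pair has a single displaced fragment: no sibling collision is possible,
  # so the on-lattice nucleus count itself is conserved
  p1 <- ssc_params(r_range = 2, lattice_sites = 1001)
  set.seed(3)
  for (i in 1:300) {
    s <- clone_state(lengths = 2L, m_prog = 0, time = 3, sites = 500L)
    out <- apply_fragmentation(s, 1, p1)
    expect_identical(sum(out$lengths), 2L)
    expect_identical(out$m_prog, 0)
  }
  # longer chains may displace several fragments into the same neighborhood;
  # a later placement can evict a sibling (which differentiates), but the
  # nucleus total n + m is conserved by every draw
  saw_sibling_eviction <- FALSE
  for (i in 1:700) {
    k <- sample(3:8, 1)
    s <- clone_state(lengths = k, m_prog = 0, time = 3, sites = 500L)
    out <- apply_fragmentation(s, 1, p1)
    expect_equal(sum(out$lengths) + out$m_prog, k)
    expect_false(anyDuplicated(out$sites) > 0)
    if (out$m_prog > 0) saw_sibling_eviction <- TRUE
  }
  expect_true(saw_sibling_eviction)
})
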