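# in-code fixtures shared across test files

# clone table from vectors of unit-length lists and m values
make_table <- function(lengths_list, m = 0, timepoint = 6,
                       prefix = "c") {
  n <- length(lengths_list)
  m <- rep_len(m, n)
  data.frame(
    clone_id = sprintf("%s%03d", prefix, seq_len(n)),
    timepoint_days = timepoint,
    composition = vapply(lengths_list, format_composition, character(1)),
    n_total = vapply(lengths_list, function(k) sum(as.integer(k)), integer(1)),
    m_prog = m,
    stringsAsFactors = FALSE)
}

# single-channel parameter sets used by the analytic-limit tests
pure_death_params <- function(gamma = 0.3, t0 = 8.1)
  ssc_params(lambda_div = 0, eta_frag = 0, gamma_loss = gamma,
             t0_loss_end = t0, mu_prog = 0)

pure_division_params <- function(lambda = 0.35)
  ssc_params(lambda_div = lambda, eta_frag = 0, gamma_loss = 0,
             mu_prog = 0)

single_cell_seeding <- function(m0 = 0)
  default_seed_distribution(1, 0, 0, m0 = m0)

# exhaustive fragment-count distribution for a length-k syncytium:
# enumerate all 2^(k-1) bridge break patterns (each equally likely)
enumerate_fragment_counts <- function(k) {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k - 1))
  counts <- apply(as.matrix(patterns), 1, sum) + 1L
  tabulate(counts, nbins = k) / nrow(patterns)
}
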