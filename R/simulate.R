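#' Simulate a single clone
#'
#' Runs the exact stochastic simulation algorithm (next event time drawn
#' from the exponential of the total propensity; event channel chosen
#' proportionally to its propensity) for one clone starting from `initial`
#' at `params$t_start`, recording snapshots at the requested times. The
#' loss-phase boundary `t0_loss_end` is treated as a barrier: a waiting time
#' sampled with the death channel active never carries the system past it;
#' the clock advances to the boundary and propensities are redrawn without
#' death, which is exact for piecewise-constant rates.
#'
#' @param initial An [clone_state()] at time `params$t_start`.
#' @param params An [ssc_params()] object.
#' @param record_times Strictly increasing times (days post-TP), all
#'   `>= params$t_start`.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first, otherwise the current RNG stream is used.
#' @return An object of class `ssc_trajectory`: list with `record_times`,
#'   `states` (one [clone_state()] per record time), `params` and `seed`.
#' @examples
#' p <- ssc_params(lambda_div = 0.3, eta_frag = 0.2, gamma_loss = 0.3,
#'                 mu_prog = 0)
#' tr <- simulate_clone(clone_state(1), p, record_times = c(2, 10, 20),
#'                      seed = 42)
#' vapply(tr$states, function(s) sum(s$lengths), numeric(1))
#' @export
simulate_clone <- function(initial, params, record_times, seed = NULL) {
  stopifnot(inherits(initial, "ssc_clone_state"),
            inherits(params, "ssc_params"))
  record_times <- as.numeric(record_times)
  if (!length(record_times))
    stop("record_times must be non-empty", call. = FALSE)
  if (any(record_times < params$t_start))
    stop("record_times must all be >= t_start", call. = FALSE)
  if (is.unsorted(record_times, strictly = TRUE))
    stop("record_times must be strictly increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  sites <- initial$sites
  if (is.null(sites))
    sites <- default_sites(length(initial$lengths), params$lattice_sites)
  res <- .simulate_clone_cpp(
    initial$lengths, sites, as.numeric(initial$m_prog),
    params$lambda_div, params$eta_frag, params$gamma_loss,
    params$t0_loss_end, params$mu_prog, params$r_range,
    params$lattice_sites, params$t_start, record_times,
    identical(params$m_mode, "stochastic"))

  states <- lapply(seq_along(record_times), function(i) {
    clone_state(lengths = res$lengths[[i]], m_prog = res$m[[i]],
                time = record_times[i])
  })
  structure(list(record_times = record_times, states = states,
                 params = params, seed = seed),
            class = "ssc_trajectory")
}

#' @export
print.ssc_trajectory <- function(x, ...) {
  n <- vapply(x$states, function(s) sum(s$lengths), numeric(1))
  m <- vapply(x$states, function(s) s$m_prog, numeric(1))
  cat("Clone trajectory:\n")
  print(data.frame(time_days = x$record_times, n_total = n, m_prog = m))
  invisible(x)
}

#' Simulate an ensemble of independent clones
#'
#' Each realization seeds one clone from `seed_distribution` at
#' `params$t_start` and simulates it on its own otherwise-empty lattice
#' (sparse limit: transplanted clones settle far apart, so inter-clone
#' collisions are negligible). Per-realization RNG substreams are derived
#' from `seed` up front, so results are bit-for-bit reproducible and
#' independent of evaluation order.
#'
#' @param seed_distribution A [seed_distribution()] over initial clone
#'   configurations.
#' @param params An [ssc_params()] object.
#' @param n_realizations Number of independent clones (>= 1).
#' @param record_times Strictly increasing record times, `>= params$t_start`.
#' @param seed Integer root seed.
#' @return An object of class `ssc_ensemble`: list with `record_times`,
#'   `n_total` and `m` matrices (`n_realizations` x times), `lengths`
#'   (per-realization list of per-time unit-length vectors), `params`,
#'   `seed`.
#' @export
simulate_ensemble <- function(seed_distribution, params, n_realizations,
                              record_times, seed) {
  stopifnot(inherits(seed_distribution, "ssc_seed_distribution"),
            inherits(params, "ssc_params"))
  n_realizations <- as.integer(n_realizations)
  if (n_realizations < 1L)
    stop("n_realizations must be >= 1", call. = FALSE)
  record_times <- as.numeric(record_times)
  if (any(record_times < params$t_start))
    stop("record_times must all be >= t_start", call. = FALSE)
  if (is.unsorted(record_times, strictly = TRUE))
    stop("record_times must be strictly increasing", call. = FALSE)

  set.seed(seed)
  cfg_idx <- sample.int(length(seed_distribution$configs), n_realizations,
                        replace = TRUE, prob = seed_distribution$weights)
  sub_seeds <- sample.int(.Machine$integer.max, n_realizations)

  nt <- length(record_times)
  n_total <- matrix(0L, n_realizations, nt)
  m <- matrix(0, n_realizations, nt)
  lengths <- vector("list", n_realizations)
  stoch <- identical(params$m_mode, "stochastic")
  for (i in seq_len(n_realizations)) {
    cfg <- seed_distribution$configs[[cfg_idx[i]]]
    sites <- default_sites(length(cfg$lengths), params$lattice_sites)
    set.seed(sub_seeds[i])
    res <- .simulate_clone_cpp(
      as.integer(cfg$lengths), sites, as.numeric(cfg$m_prog),
      params$lambda_div, params$eta_frag, params$gamma_loss,
      params$t0_loss_end, params$mu_prog, params$r_range,
      params$lattice_sites, params$t_start, record_times, stoch)
    n_total[i, ] <- res$n_total
    m[i, ] <- res$m
    lengths[[i]] <- res$lengths
  }
  structure(list(record_times = record_times, n_total = n_total, m = m,
                 lengths = lengths, params = params, seed = seed),
            class = "ssc_ensemble")
}

#' @export
print.ssc_ensemble <- function(x, ...) {
  cat(sprintf("Clone ensemble: %d realizations, %d record times (seed %s)\n",
              nrow(x$n_total), length(x$record_times),
              format(x$seed)))
  s <- colMeans(x$n_total >= 1L)
  cat("  survival by time:",
      paste(sprintf("t=%g: %.3f", x$record_times, s), collapse = "  "), "\n")
  invisible(x)
}

#' Flatten an ensemble into a cross-sectional clone table
#'
#' Produces one row per (realization, record time) in the on-disk clone
#' table layout: `clone_id`, `timepoint_days`, `composition` ("k:count"
#' pairs, ascending k, joined by ";"), `n_total`, `m_prog`. Because the
#' study design is cross-sectional, consumers treat rows at different
#' timepoints as independent clones even when they came from one simulated
#' trajectory.
#'
#' @param ensemble An `ssc_ensemble`.
#' @param id_prefix Prefix for generated clone ids.
#' @return A data frame.
#' @export
ensemble_to_table <- function(ensemble, id_prefix = "sim") {
  stopifnot(inherits(ensemble, "ssc_ensemble"))
  nreal <- nrow(ensemble$n_total)
  nt <- length(ensemble$record_times)
  rows <- vector("list", nt)
  for (j in seq_len(nt)) {
    comp <- vapply(seq_len(nreal),
                   function(i) format_composition(ensemble$lengths[[i]][[j]]),
                   character(1))
    rows[[j]] <- data.frame(
      clone_id = sprintf("%s_t%g_c%04d", id_prefix,
                         ensemble$record_times[j], seq_len(nreal)),
      timepoint_days = ensemble$record_times[j],
      composition = comp,
      n_total = ensemble$n_total[, j],
      m_prog = ensemble$m[, j],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
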