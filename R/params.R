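#' Model parameters for the clone dynamics simulator
#'
#' Bundles all rates and lattice settings of the stochastic clone model.
#' Units are days and lattice sites throughout; times are days
#' post-transplantation.
#'
#' The default rate values are placeholders on the scale expected for
#' regenerating spermatogonial clones (divisions every few days); only the
#' loss-phase length default (8.1 days) is an externally anchored value.
#' Always set rates explicitly for quantitative work.
#'
#' @param lambda_div Incomplete-division rate per GFRa1+ unit per day.
#'   Each division doubles the unit's syncytial length in place (k to 2k).
#' @param eta_frag Fragmentation rate per intercellular bridge per day; a
#'   unit of length k fragments at total rate `(k - 1) * eta_frag`.
#' @param gamma_loss Death rate per GFRa1+ unit per day, active only while
#'   `t < t0_loss_end`.
#' @param t0_loss_end End of the initial loss phase, days post-transplantation.
#' @param mu_prog Net proliferation rate per GFRa1- cell per day.
#' @param r_range Displacement neighborhood half-width: displaced fragments
#'   land uniformly among the `2 * r_range` sites within +/- `r_range` of the
#'   origin site.
#' @param t_start Simulation start time, days post-transplantation.
#' @param lattice_sites Number of sites on the periodic 1D lattice. The
#'   default (10000) is large enough that a clone never self-wraps over the
#'   simulated timescales.
#' @param seed Optional integer seed stored with the parameters; functions
#'   accepting an explicit `seed` argument ignore this field.
#' @param m_mode `"stochastic"` for an exact pure-birth (Yule) GFRa1- pool,
#'   or `"deterministic"` to propagate its expectation
#'   `m(t + dt) = m(t) exp(mu_prog dt)` between events (much faster when the
#'   progeny pool grows large; GFRa1+ dynamics are unaffected).
#'
#' @return An object of class `ssc_params`.
#' @examples
#' p <- ssc_params(lambda_div = 0.3, eta_frag = 0.2, gamma_loss = 0.3,
#'                 t0_loss_end = 8.1, mu_prog = 0.4)
#' p
#' @export
ssc_params <- function(lambda_div = 0.35, eta_frag = 0.25, gamma_loss = 0.3,
                       t0_loss_end = 8.1, mu_prog = 0.35, r_range = 1L,
                       t_start = 2, lattice_sites = 10000L, seed = NULL,
                       m_mode = c("stochastic", "deterministic")) {
  m_mode <- match.arg(m_mode)
  rates <- c(lambda_div = lambda_div, eta_frag = eta_frag,
             gamma_loss = gamma_loss, mu_prog = mu_prog)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (!is.finite(t_start) || !is.finite(t0_loss_end))
    stop("t_start and t0_loss_end must be finite", call. = FALSE)
  if (t0_loss_end < t_start)
    stop("t0_loss_end must be >= t_start", call. = FALSE)
  r_range <- as.integer(r_range)
  lattice_sites <- as.integer(lattice_sites)
  if (r_range < 1L) stop("r_range must be >= 1", call. = FALSE)
  if (lattice_sites < 2L * r_range + 1L)
    stop("lattice_sites must be >= 2 * r_range + 1", call. = FALSE)
  structure(list(lambda_div = lambda_div, eta_frag = eta_frag,
                 gamma_loss = gamma_loss, t0_loss_end = t0_loss_end,
                 mu_prog = mu_prog, r_range = r_range, t_start = t_start,
                 lattice_sites = lattice_sites, seed = seed,
                 m_mode = m_mode),
            class = "ssc_params")
}

#' @export
print.ssc_params <- function(x, ...) {
  cat("Clone-model parameters (rates per day, times in days post-TP)\n")
  cat(sprintf("  division lambda     : %.4g /unit\n", x$lambda_div))
  cat(sprintf("  fragmentation eta   : %.4g /bridge\n", x$eta_frag))
  cat(sprintf("  loss gamma          : %.4g /unit (t < %.4g)\n",
              x$gamma_loss, x$t0_loss_end))
  cat(sprintf("  progenitor mu       : %.4g /cell (%s)\n", x$mu_prog, x$m_mode))
  cat(sprintf("  lattice             : %d sites (ring), r = %d\n",
              x$lattice_sites, x$r_range))
  cat(sprintf("  t_start             : %.4g\n", x$t_start))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-running
#' validation.
#'
#' @param params An [ssc_params()] object.
#' @param ... Named fields to replace.
#' @return An `ssc_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "ssc_params"))
  new <- utils::modifyList(unclass(params), list(...))
  do.call(ssc_params, new)
}

#' Single-clone state
#'
#' A clone state is the multiset of GFRa1+ syncytial unit lengths (each unit
#' occupying one lattice site) plus the off-lattice GFRa1- cell count.
#'
#' @param lengths Integer vector of unit lengths (k >= 1), one entry per
#'   syncytial unit; may be empty for an extinct clone.
#' @param m_prog GFRa1- cell count (>= 0).
#' @param time Time of the state, days post-transplantation.
#' @param sites Optional integer vector of lattice sites (same length as
#'   `lengths`, all distinct). If `NULL`, units are placed on consecutive
#'   sites around the lattice midpoint when a simulation starts.
#' @return An object of class `ssc_clone_state`.
#' @examples
#' clone_state(lengths = c(1, 2, 4), m_prog = 3)
#' @export
clone_state <- function(lengths = 1L, m_prog = 0, time = 2, sites = NULL) {
  lengths <- as.integer(lengths)
  if (length(lengths) && any(lengths < 1L))
    stop("unit lengths must be >= 1", call. = FALSE)
  if (m_prog < 0) stop("m_prog must be >= 0", call. = FALSE)
  if (!is.null(sites)) {
    sites <- as.integer(sites)
    if (length(sites) != length(lengths))
      stop("sites must match lengths", call. = FALSE)
    if (anyDuplicated(sites))
      stop("two units cannot share a lattice site", call. = FALSE)
  }
  structure(list(lengths = lengths, m_prog = m_prog, time = time,
                 sites = sites),
            class = "ssc_clone_state")
}

#' @export
print.ssc_clone_state <- function(x, ...) {
  cat(sprintf("Clone state at t = %.4g d: %d unit(s) [%s], n = %d, m = %.4g\n",
              x$time, length(x$lengths),
              paste(x$lengths, collapse = ","),
              sum(x$lengths), x$m_prog))
  invisible(x)
}

# default placement: consecutive sites centred on the ring
default_sites <- function(n_units, lattice_sites) {
  if (n_units == 0L) return(integer(0))
  mid <- lattice_sites %/% 2L
  (mid + seq_len(n_units) - 1L) %% lattice_sites
}
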