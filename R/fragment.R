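#' Draw fragment lengths for a fragmenting syncytium
#'
#' A syncytium of length `length_k` has `length_k - 1` intercellular
#' bridges. On a fragmentation event each bridge breaks independently with
#' probability 1/2; the fragments are the maximal runs of nuclei between
#' broken bridges. A draw in which no bridge breaks is a valid outcome and
#' returns the intact unit.
#'
#' @param length_k Integer >= 2, syncytial length of the fragmenting unit.
#' @param breaks Optional logical vector of length `length_k - 1` forcing
#'   the bridge states (`TRUE` = broken); by default each bridge state is
#'   drawn Bernoulli(1/2) from the current RNG stream.
#' @return Integer vector of fragment lengths, in nucleus order, summing to
#'   `length_k`.
#' @examples
#' set.seed(1)
#' fragment_lengths(4)
#' fragment_lengths(4, breaks = c(TRUE, FALSE, TRUE))  # 1 + 2 + 1
#' @export
fragment_lengths <- function(length_k, breaks = NULL) {
  length_k <- as.integer(length_k)
  if (length(length_k) != 1L || length_k < 2L)
    stop("length_k must be a single integer >= 2 (a 1-unit has no bridges)",
         call. = FALSE)
  if (is.null(breaks)) {
    breaks <- runif(length_k - 1L) < 0.5
  } else {
    breaks <- as.logical(breaks)
    if (length(breaks) != length_k - 1L)
      stop("breaks must have length length_k - 1", call. = FALSE)
  }
  as.integer(diff(c(0L, which(breaks), length_k)))
}

#' Event propensities of a clone state
#'
#' Tabulates the instantaneous rates of all event channels for a clone
#' state: per-unit incomplete division (rate `lambda_div` each), per-unit
#' fragmentation (rate `(k - 1) * eta_frag`), per-unit death (rate
#' `gamma_loss` while `time < t0_loss_end`, zero afterwards) and the total
#' progenitor-birth rate `m_prog * mu_prog`.
#'
#' @param state An [clone_state()] object.
#' @param params An [ssc_params()] object.
#' @return A data frame with columns `event` (channel name), `target`
#'   (unit index, `NA` for the progenitor channel) and `rate`; the summed
#'   propensity is attached as attribute `"total"`. An extinct clone with
#'   `m_prog = 0` yields an empty table with total 0.
#' @examples
#' s <- clone_state(lengths = c(1, 2, 4), m_prog = 3, time = 4)
#' p <- event_propensities(s, ssc_params(lambda_div = 1, eta_frag = 1,
#'                                       gamma_loss = 1, mu_prog = 1))
#' attr(p, "total")  # 3 + 4 + 3 + 3
#' @export
event_propensities <- function(state, params) {
  stopifnot(inherits(state, "ssc_clone_state"), inherits(params, "ssc_params"))
  k <- state$lengths
  U <- length(k)
  death_on <- state$time < params$t0_loss_end
  tab <- data.frame(
    event = c(rep("division", U), rep("fragmentation", U),
              rep("death", U), "progenitor_birth"),
    target = c(seq_len(U), seq_len(U), seq_len(U), NA_integer_),
    rate = c(rep(params$lambda_div, U),
             (k - 1) * params$eta_frag,
             rep(if (death_on) params$gamma_loss else 0, U),
             state$m_prog * params$mu_prog),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$rate > 0 | tab$event == "progenitor_birth", , drop = FALSE]
  if (U == 0L && state$m_prog == 0)
    tab <- tab[0L, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "total") <- sum(tab$rate)
  tab
}

#' Apply one fragmentation event to a clone state
#'
#' Reference R implementation of the fragmentation/migration/differentiation
#' move (the compiled simulator applies the same rule internally). Fragment
#' lengths are drawn by [fragment_lengths()]; one uniformly chosen fragment
#' keeps the origin site; every other fragment is displaced to a site drawn
#' uniformly among the `2 * r_range` sites within +/- `r_range` of the
#' origin (origin excluded), in uniformly random placement order. A
#' displaced fragment landing on an occupied site differentiates the
#' occupant: the occupant's nuclei leave the lattice and join `m_prog`.
#' Total nuclei (on-lattice n plus the differentiation gain of m) are
#' conserved.
#'
#' @param state An [clone_state()] object with explicit `sites`.
#' @param unit Index of the fragmenting unit in `state$lengths`; its length
#'   must be >= 2.
#' @param params An [ssc_params()] object.
#' @param breaks Optional forced bridge states, passed to
#'   [fragment_lengths()].
#' @return The post-event `ssc_clone_state`.
#' @export
apply_fragmentation <- function(state, unit, params, breaks = NULL) {
  stopifnot(inherits(state, "ssc_clone_state"), inherits(params, "ssc_params"))
  U <- length(state$lengths)
  if (!(unit %in% seq_len(U)))
    stop("unit is not part of the state", call. = FALSE)
  if (state$lengths[unit] < 2L)
    stop("a 1-unit has no bridges and cannot fragment", call. = FALSE)
  sites <- state$sites
  if (is.null(sites)) sites <- default_sites(U, params$lattice_sites)
  lengths <- state$lengths
  m <- state$m_prog
  L <- params$lattice_sites
  r <- params$r_range

  frags <- fragment_lengths(lengths[unit], breaks = breaks)
  nf <- length(frags)
  origin <- sites[unit]
  if (nf > 1L) {
    stay <- sample.int(nf, 1L)
    lengths[unit] <- frags[stay]
    disp <- frags[-stay]
    disp <- disp[sample.int(length(disp))]  # random placement order
    for (fk in disp) {
      j <- sample.int(2L * r, 1L)
      off <- if (j <= r) j else -(j - r)
      s <- (origin + off) %% L
      hit <- which(sites == s)
      if (length(hit)) {
        # former occupant differentiates into the GFRa1- pool
        m <- m + lengths[hit]
        lengths <- lengths[-hit]
        sites <- sites[-hit]
      }
      lengths <- c(lengths, fk)
      sites <- c(sites, s)
    }
  }
  clone_state(lengths = lengths, m_prog = m, time = state$time, sites = sites)
}
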