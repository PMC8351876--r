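#' Default syncytial length bins
#'
#' Standard reporting bins for syncytial composition: singly isolated cells
#' (A_s, k = 1), pairs (A_pr, k = 2), and aligned chains binned at 4, 8 and
#' beyond (A_al4: k in 3..4, A_al8: k in 5..8, A_al16+: k >= 9).
#'
#' @param upper Upper edges of the bins (last may be `Inf`).
#' @param labels Bin labels, same length as `upper`.
#' @return A list with `upper` and `labels`, class `ssc_bins`.
#' @export
ssc_bins <- function(upper = c(1, 2, 4, 8, Inf),
                     labels = c("A_s", "A_pr", "A_al4", "A_al8", "A_al16+")) {
  if (length(upper) != length(labels))
    stop("upper and labels must have the same length", call. = FALSE)
  if (is.unsorted(upper, strictly = TRUE))
    stop("upper edges must be strictly increasing", call. = FALSE)
  structure(list(upper = upper, labels = labels), class = "ssc_bins")
}

bin_unit_lengths <- function(k, bins) {
  # counts of units per bin
  idx <- findInterval(k, c(0, bins$upper), left.open = TRUE)
  tabulate(idx, nbins = length(bins$upper))
}

subset_time <- function(observations, timepoint) {
  stopifnot(is.data.frame(observations))
  out <- observations[observations$timepoint_days == timepoint, , drop = FALSE]
  if (!nrow(out))
    stop(sprintf("no observations at timepoint %g", timepoint), call. = FALSE)
  out
}

#' Clone survival fraction
#'
#' Fraction of clones that retain at least one GFRa1+ cell ("persisting
#' clones") at a timepoint: `S(t) = 1 - P(0, t)` where `P(n, t)` is the
#' marginal distribution of the total GFRa1+ cell number.
#'
#' @param observations A clone table (data frame with at least
#'   `timepoint_days` and `n_total`).
#' @param timepoint Timepoint (days post-TP) to evaluate.
#' @return Survival fraction in \[0, 1\].
#' @examples
#' tab <- data.frame(timepoint_days = 6, n_total = c(0, 2, 5, 0))
#' survival_fraction(tab, 6)  # 0.5
#' @export
survival_fraction <- function(observations, timepoint) {
  obs <- subset_time(observations, timepoint)
  mean(obs$n_total >= 1)
}

#' Mean persisting clone size
#'
#' Average GFRa1+ cell content among persisting clones (those with
#' `n_total >= 1`); extinct clones are excluded, i.e. the mean of the
#' survival-normalized subdistribution of clone sizes.
#'
#' @inheritParams survival_fraction
#' @return Mean n over persisting clones.
#' @export
mean_persisting_size <- function(observations, timepoint) {
  obs <- subset_time(observations, timepoint)
  n <- obs$n_total[obs$n_total >= 1]
  if (!length(n))
    stop(sprintf("no persisting clones at timepoint %g; mean size undefined",
                 timepoint), call. = FALSE)
  mean(n)
}

#' Cumulative size distribution of persisting clones
#'
#' Empirical cumulative distribution of the GFRa1+ cell number among
#' persisting clones at a timepoint.
#'
#' @inheritParams survival_fraction
#' @return A data frame with columns `n` (sorted unique sizes) and `cdf`
#'   (non-decreasing, reaching 1 at the largest size).
#' @export
persisting_size_cdf <- function(observations, timepoint) {
  obs <- subset_time(observations, timepoint)
  n <- obs$n_total[obs$n_total >= 1]
  if (!length(n))
    stop(sprintf("no persisting clones at timepoint %g", timepoint),
         call. = FALSE)
  tab <- table(n)
  data.frame(n = as.integer(names(tab)),
             cdf = cumsum(as.integer(tab)) / length(n))
}

#' Mean GFRa1- progeny per clone
#'
#' Unconditional mean of the GFRa1- cell count over all clones at a
#' timepoint, including clones that no longer contain GFRa1+ cells.
#'
#' @inheritParams survival_fraction
#' @return Mean m over all clones.
#' @export
mean_progeny <- function(observations, timepoint) {
  obs <- subset_time(observations, timepoint)
  bad <- is.na(obs$m_prog)
  if (any(bad))
    stop(sprintf("m_prog missing for clone(s): %s",
                 paste(obs$clone_id[bad], collapse = ", ")), call. = FALSE)
  mean(obs$m_prog)
}

#' Ensemble syncytial composition
#'
#' Relative frequencies of syncytial unit lengths pooled across all clones
#' at a timepoint: `r_k = <n_k> / sum_j <n_j>`, the ensemble-average
#' occupation of each length class normalized over classes. Units (not
#' nuclei) are counted, and clones contribute in proportion to their unit
#' numbers.
#'
#' @inheritParams survival_fraction
#' @param bins An [ssc_bins()] object, or `NULL` for raw per-length
#'   frequencies.
#' @return Named numeric vector summing to 1.
#' @export
syncytial_composition <- function(observations, timepoint,
                                  bins = ssc_bins()) {
  obs <- subset_time(observations, timepoint)
  lens <- unlist(lapply(obs$composition, function(cmp) {
    cc <- parse_composition(cmp)
    rep(as.integer(names(cc)), cc)
  }), use.names = FALSE)
  if (!length(lens))
    stop(sprintf("no GFRa1+ units at timepoint %g", timepoint), call. = FALSE)
  if (is.null(bins)) {
    tab <- table(lens)
    return(setNames(as.numeric(tab) / length(lens), names(tab)))
  }
  cnt <- bin_unit_lengths(lens, bins)
  setNames(cnt / sum(cnt), bins$labels)
}

#' Ensemble statistics per timepoint
#'
#' Computes the full cross-sectional observable set at each timepoint:
#' survival fraction, mean persisting clone size, mean GFRa1- progeny,
#' binned syncytial composition, and the persisting-size CDF. Works on a
#' clone table (data frame) or directly on a simulated
#' [simulate_ensemble()] object; both routes produce identical statistics
#' for the same underlying clones.
#'
#' @param x A clone table data frame or an `ssc_ensemble`.
#' @param bins An [ssc_bins()] object for composition reporting.
#' @param ... Unused.
#' @return An object of class `ssc_stats`: list with `summary` (data frame
#'   with columns `timepoint_days`, `n_clones`, `S`, `mean_n_persisting`,
#'   `mean_m`), `composition` (timepoints x bins matrix of row-normalized
#'   frequencies; a row is all-`NA` when no units exist), and `cdf` (named
#'   list of per-timepoint CDF data frames, `NULL` where no clone persists).
#' @export
ensemble_statistics <- function(x, bins = ssc_bins(), ...) {
  UseMethod("ensemble_statistics")
}

stats_from_columns <- function(timepoints, n_by_t, m_by_t, lens_by_t, bins) {
  nt <- length(timepoints)
  S <- mean_n <- mean_m <- rep(NA_real_, nt)
  n_clones <- integer(nt)
  comp <- matrix(NA_real_, nt, length(bins$upper),
                 dimnames = list(format(timepoints), bins$labels))
  cdfs <- vector("list", nt)
  names(cdfs) <- format(timepoints)
  for (j in seq_len(nt)) {
    n <- n_by_t[[j]]
    n_clones[j] <- length(n)
    S[j] <- mean(n >= 1)
    pers <- n[n >= 1]
    if (length(pers)) {
      mean_n[j] <- mean(pers)
      tab <- table(pers)
      cdfs[[j]] <- data.frame(n = as.integer(names(tab)),
                              cdf = cumsum(as.integer(tab)) / length(pers))
    }
    m <- m_by_t[[j]]
    if (!anyNA(m)) mean_m[j] <- mean(m)
    lens <- lens_by_t[[j]]
    if (length(lens)) {
      cnt <- bin_unit_lengths(lens, bins)
      comp[j, ] <- cnt / sum(cnt)
    }
  }
  structure(list(
    summary = data.frame(timepoint_days = timepoints, n_clones = n_clones,
                         S = S, mean_n_persisting = mean_n, mean_m = mean_m),
    composition = comp,
    cdf = cdfs,
    bins = bins), class = "ssc_stats")
}

#' @rdname ensemble_statistics
#' @export
ensemble_statistics.data.frame <- function(x, bins = ssc_bins(), ...) {
  timepoints <- sort(unique(x$timepoint_days))
  n_by_t <- m_by_t <- lens_by_t <- vector("list", length(timepoints))
  for (j in seq_along(timepoints)) {
    obs <- x[x$timepoint_days == timepoints[j], , drop = FALSE]
    n_by_t[[j]] <- obs$n_total
    m_by_t[[j]] <- if ("m_prog" %in% names(obs)) obs$m_prog
                   else rep(NA_real_, nrow(obs))
    lens_by_t[[j]] <- unlist(lapply(obs$composition, function(cmp) {
      cc <- parse_composition(cmp)
      rep(as.integer(names(cc)), cc)
    }), use.names = FALSE)
  }
  stats_from_columns(timepoints, n_by_t, m_by_t, lens_by_t, bins)
}

#' @rdname ensemble_statistics
#' @export
ensemble_statistics.ssc_ensemble <- function(x, bins = ssc_bins(), ...) {
  nt <- length(x$record_times)
  nreal <- nrow(x$n_total)
  n_by_t <- m_by_t <- lens_by_t <- vector("list", nt)
  for (j in seq_len(nt)) {
    n_by_t[[j]] <- x$n_total[, j]
    m_by_t[[j]] <- x$m[, j]
    lens_by_t[[j]] <- unlist(lapply(seq_len(nreal),
                                    function(i) x$lengths[[i]][[j]]),
                             use.names = FALSE)
  }
  stats_from_columns(x$record_times, n_by_t, m_by_t, lens_by_t, bins)
}

#' @export
print.ssc_stats <- function(x, ...) {
  cat("Ensemble statistics:\n")
  print(x$summary, row.names = FALSE)
  cat("Syncytial composition (unit fractions):\n")
  print(round(x$composition, 3))
  invisible(x)
}
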