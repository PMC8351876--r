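#' Distribution over initial clone configurations
#'
#' A seed distribution assigns probabilities to the possible states of a
#' freshly settled clone at simulation start: each configuration is a set
#' of syncytial unit lengths plus an initial GFRa1- count.
#'
#' @param configs List of configurations, each a list with `lengths`
#'   (integer vector, one entry per unit) and `m_prog` (>= 0).
#' @param weights Non-negative weights, one per configuration; normalized
#'   to sum to 1.
#' @return An object of class `ssc_seed_distribution`.
#' @export
seed_distribution <- function(configs, weights) {
  if (!length(configs)) stop("empty seed distribution", call. = FALSE)
  if (length(weights) != length(configs))
    stop("weights must match configs", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be >= 0 and sum to > 0", call. = FALSE)
  configs <- lapply(configs, function(cfg) {
    list(lengths = as.integer(cfg$lengths),
         m_prog = if (is.null(cfg$m_prog)) 0 else cfg$m_prog)
  })
  structure(list(configs = configs, weights = weights / sum(weights)),
            class = "ssc_seed_distribution")
}

#' Default parametric seed distribution
#'
#' Parametric stand-in for the clone composition observed two days after
#' transplantation: mostly single cells, some pairs, and a small fraction
#' of longer chains (syncytia are observed as early as day 2). The weights
#' are placeholders for the study-specific empirical distribution; override
#' them, or use [empirical_seed_distribution()] on real day-2 data.
#'
#' @param p_single,p_pair,p_chain4 Mixture weights for a single A_s, an
#'   A_pr pair, and an A_al chain of 4; normalized internally.
#' @param m0 Initial GFRa1- count given to every configuration.
#' @return An `ssc_seed_distribution`.
#' @export
default_seed_distribution <- function(p_single = 0.7, p_pair = 0.2,
                                      p_chain4 = 0.1, m0 = 0) {
  seed_distribution(
    configs = list(list(lengths = 1L, m_prog = m0),
                   list(lengths = 2L, m_prog = m0),
                   list(lengths = 4L, m_prog = m0)),
    weights = c(p_single, p_pair, p_chain4))
}

#' Empirical seed distribution from observed clones
#'
#' Builds a seed distribution from the observed clone states at one
#' timepoint (normally the earliest harvest), so that simulations started
#' from it coincide with the data at that time by construction. Each
#' distinct observed (composition, m) state becomes one configuration
#' weighted by its frequency. Missing m values are treated as 0.
#'
#' @param observations A clone table data frame.
#' @param timepoint Timepoint whose clones define the distribution.
#' @return An `ssc_seed_distribution`.
#' @export
empirical_seed_distribution <- function(observations, timepoint) {
  obs <- subset_time(observations, timepoint)
  m <- ifelse(is.na(obs$m_prog), 0, obs$m_prog)
  key <- paste(obs$composition, m, sep = "|")
  tab <- table(key)
  configs <- lapply(names(tab), function(kk) {
    parts <- strsplit(kk, "|", fixed = TRUE)[[1]]
    cc <- parse_composition(parts[1])
    list(lengths = rep(as.integer(names(cc)), cc),
         m_prog = as.numeric(parts[2]))
  })
  seed_distribution(configs, as.numeric(tab))
}

#' Cross-sectional study design
#'
#' Describes a synthetic lineage-tracing transplantation study: a set of
#' harvest timepoints, the number of observed clones per harvest, the
#' ground-truth model parameters and the seeding distribution. The design
#' is cross-sectional: hosts are sacrificed at each harvest, so every
#' timepoint samples an independent clone ensemble.
#'
#' @param harvest_times Harvest timepoints, days post-TP (all
#'   `>= truth$t_start`).
#' @param clones_per_time Clones observed per harvest (default 300, the
#'   order of labeled clones settling per host cohort).
#' @param truth An [ssc_params()] object: the generating parameters.
#' @param seed_dist An [seed_distribution()] for clone initialization.
#' @param dropout Per-clone probability of being lost to observation at
#'   each harvest (0 = the model's own noise-free reporting).
#' @param seed Integer root seed.
#' @return An object of class `ssc_design`.
#' @export
study_design <- function(harvest_times = c(2, 6, 10, 14, 20),
                         clones_per_time = 300,
                         truth = ssc_params(),
                         seed_dist = default_seed_distribution(),
                         dropout = 0,
                         seed = 1) {
  stopifnot(inherits(truth, "ssc_params"),
            inherits(seed_dist, "ssc_seed_distribution"))
  clones_per_time <- as.integer(clones_per_time)
  if (clones_per_time < 1L) stop("clones_per_time must be >= 1",
                                 call. = FALSE)
  if (any(harvest_times < truth$t_start))
    stop("harvest times must be >= truth$t_start", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(harvest_times = sort(unique(harvest_times)),
                 clones_per_time = clones_per_time, truth = truth,
                 seed_dist = seed_dist, dropout = dropout, seed = seed),
            class = "ssc_design")
}

#' Generate a synthetic clone-observation table
#'
#' Simulates, for each harvest timepoint, an independent ensemble of clones
#' from `design$truth` and reports their cross-sectional states in the
#' clone-table exchange format, together with a manifest recording the
#' generating parameters and seed (for parameter-recovery experiments).
#' Output is byte-identical across runs with the same design.
#'
#' @param design An [study_design()] object.
#' @return A list with `table` (data frame, one row per clone per harvest)
#'   and `manifest` (list: `truth`, `seed`, `harvest_times`,
#'   `clones_per_time`, `dropout`).
#' @examples
#' d <- study_design(harvest_times = c(2, 6), clones_per_time = 20, seed = 7)
#' ds <- generate_dataset(d)
#' head(ds$table)
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "ssc_design"))
  set.seed(design$seed)
  time_seeds <- sample.int(.Machine$integer.max, length(design$harvest_times))
  drop_seeds <- sample.int(.Machine$integer.max, length(design$harvest_times))
  rows <- vector("list", length(design$harvest_times))
  for (j in seq_along(design$harvest_times)) {
    tj <- design$harvest_times[j]
    ens <- simulate_ensemble(design$seed_dist, design$truth,
                             design$clones_per_time, record_times = tj,
                             seed = time_seeds[j])
    comp <- vapply(seq_len(design$clones_per_time),
                   function(i) format_composition(ens$lengths[[i]][[1]]),
                   character(1))
    df <- data.frame(
      clone_id = sprintf("TP%g_c%04d", tj, seq_len(design$clones_per_time)),
      timepoint_days = tj,
      composition = comp,
      n_total = ens$n_total[, 1],
      m_prog = ens$m[, 1],
      stringsAsFactors = FALSE)
    if (design$dropout > 0) {
      set.seed(drop_seeds[j])
      keep <- runif(nrow(df)) >= design$dropout
      df <- df[keep, , drop = FALSE]
    }
    rows[[j]] <- df
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validate_clone_table(tab)
  list(table = tab,
       manifest = list(truth = unclass(design$truth)[
                         c("lambda_div", "eta_frag", "gamma_loss",
                           "t0_loss_end", "mu_prog", "r_range", "t_start",
                           "lattice_sites", "m_mode")],
                       seed = design$seed,
                       harvest_times = design$harvest_times,
                       clones_per_time = design$clones_per_time,
                       dropout = design$dropout))
}
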