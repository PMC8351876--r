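#' Clone-merger probability for randomly settled clusters
#'
#' After transplantation, labeled clusters settle at random positions along
#' the seminiferous tubules. For `N` clusters of mean spatial extent `a`
#' (mm) placed uniformly along tubule length `L` (mm), the probability that
#' a given cluster overlaps (merges with) at least one other is
#' approximately `p = 1 - (1 - a/L)^(N - 1)`.
#'
#' @param n_clusters Mean number of clusters N (>= 1).
#' @param mean_extent_a Mean cluster extent a in mm (0 < a <= L).
#' @param tubule_length_L Total tubule length L in mm.
#' @return Exact probability in \[0, 1\].
#' @examples
#' merger_probability(6, 1.2, 1700)           # ~0.0035
#' report_probability(merger_probability(6, 1.2, 1700))  # 0.004
#' @export
merger_probability <- function(n_clusters, mean_extent_a, tubule_length_L) {
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (mean_extent_a <= 0 || tubule_length_L <= 0)
    stop("extents must be positive", call. = FALSE)
  if (mean_extent_a > tubule_length_L)
    stop("mean cluster extent cannot exceed the tubule length", call. = FALSE)
  1 - (1 - mean_extent_a / tubule_length_L)^(n_clusters - 1)
}

#' Report a probability to one significant figure
#'
#' Reporting helper matching the convention of quoting small merger
#' probabilities to a single significant figure (0.0035... is reported as
#' 0.004).
#'
#' @param p Probability.
#' @return `signif(p, 1)`.
#' @export
report_probability <- function(p) signif(p, 1)

#' Labeling efficiency
#'
#' Fraction of a reference cell population carrying the lineage label,
#' `labeled_count / reference_count`.
#'
#' @param labeled_count Number of labeled cells.
#' @param reference_count Size of the reference population (> 0).
#' @return The fraction; its percent rendering (one decimal) is attached
#'   as attribute `"percent"`.
#' @examples
#' labeling_efficiency(1529, 5499)  # 0.278 -> "27.8%"
#' @export
labeling_efficiency <- function(labeled_count, reference_count) {
  if (reference_count <= 0)
    stop("reference_count must be > 0", call. = FALSE)
  if (labeled_count < 0) stop("labeled_count must be >= 0", call. = FALSE)
  f <- labeled_count / reference_count
  attr(f, "percent") <- sprintf("%.1f%%", 100 * f)
  f
}

#' Injected-cell budget
#'
#' Arithmetic chain estimating how many marker-positive and how many
#' labeled cells were injected per host testis in a transplantation assay.
#'
#' The total marker-positive pool per testis is either
#' `gfra1_density * tubule_length` (the GFRa1 route), or that total scaled
#' by `rarg_pos_frac / gfra1_pos_frac` (the Ngn3 route: Ngn3+ spermatogonia
#' exclusively express Rarg, so the Rarg+/GFRa1+ fractions of A_undiff
#' convert the GFRa1+ total into an Ngn3+ total). Then
#' `injected_marker_pos = total * (injected_total / testis_cell_total) *
#' viability`, and `injected_labeled = injected_marker_pos *
#' labeling_efficiency / marker_pos_fraction_in_labeled`. All values are
#' carried exactly and rounded to whole cells only in the reported result;
#' the unrounded chain is attached as attribute `"exact"`.
#'
#' @param gfra1_density GFRa1+ cell density along tubules, cells/mm.
#' @param tubule_length Total tubule length per testis, mm.
#' @param testis_cell_total Total cells per donor testis.
#' @param injected_total Cells injected per host testis.
#' @param viability Viable fraction of the injected suspension, in \[0, 1\].
#' @param labeling_efficiency Fraction of the marker population labeled,
#'   in \[0, 1\] (see [labeling_efficiency()]).
#' @param marker_pos_fraction_in_labeled Fraction of labeled cells that are
#'   marker-positive, in (0, 1\].
#' @param route `"gfra1"` or `"ngn3"`.
#' @param rarg_pos_frac,gfra1_pos_frac Fractions of Rarg+ and GFRa1+ cells
#'   among undifferentiated spermatogonia (Ngn3 route only).
#' @return List with `total_per_testis`, `injected_marker_pos`,
#'   `injected_labeled`, rounded to whole cells; attribute `"exact"` keeps
#'   the unrounded values.
#' @examples
#' b <- injected_cell_budget(labeling_efficiency = 0.278,
#'                           marker_pos_fraction_in_labeled = 0.804)
#' b$total_per_testis     # 57800
#' b$injected_marker_pos  # 3094
#' b$injected_labeled     # 1070
#' @export
injected_cell_budget <- function(gfra1_density = 34, tubule_length = 1700,
                                 testis_cell_total = 18.4e6,
                                 injected_total = 1e6, viability = 0.985,
                                 labeling_efficiency,
                                 marker_pos_fraction_in_labeled,
                                 route = c("gfra1", "ngn3"),
                                 rarg_pos_frac = 0.62,
                                 gfra1_pos_frac = 0.49) {
  route <- match.arg(route)
  fracs <- c(viability, labeling_efficiency, marker_pos_fraction_in_labeled)
  if (any(fracs < 0 | fracs > 1))
    stop("viability, labeling efficiency and marker fraction must be in [0, 1]",
         call. = FALSE)
  if (testis_cell_total <= 0)
    stop("testis_cell_total must be > 0", call. = FALSE)
  if (marker_pos_fraction_in_labeled <= 0)
    stop("marker_pos_fraction_in_labeled must be > 0", call. = FALSE)
  total <- gfra1_density * tubule_length
  if (route == "ngn3") {
    if (gfra1_pos_frac <= 0)
      stop("gfra1_pos_frac must be > 0", call. = FALSE)
    total <- total * rarg_pos_frac / gfra1_pos_frac
  }
  injected <- total * (injected_total / testis_cell_total) * viability
  labeled <- injected * labeling_efficiency / marker_pos_fraction_in_labeled
  out <- list(total_per_testis = round(total),
              injected_marker_pos = round(injected),
              injected_labeled = round(labeled))
  attr(out, "exact") <- list(total_per_testis = total,
                             injected_marker_pos = injected,
                             injected_labeled = labeled)
  out
}
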