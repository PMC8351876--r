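#' Composition strings
#'
#' The clone-table exchange format stores the syncytial composition of a
#' clone as `"k:count"` pairs joined by `";"`, with ascending k, e.g.
#' `"1:3;2:1"` for three singles and one pair. An extinct clone (no GFRa1+
#' units) is the empty string.
#'
#' @param lengths Integer vector of unit lengths (one entry per unit).
#' @return `format_composition()`: a single string. `parse_composition()`:
#'   a named integer vector of counts, names = lengths (ascending), empty
#'   for the empty string.
#' @examples
#' format_composition(c(1, 1, 2, 1))   # "1:3;2:1"
#' parse_composition("1:3;2:1")
#' @export
format_composition <- function(lengths) {
  lengths <- as.integer(lengths)
  if (!length(lengths)) return("")
  tab <- table(lengths)
  paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ";")
}

#' @rdname format_composition
#' @param x A composition string.
#' @export
parse_composition <- function(x) {
  if (is.na(x) || !nzchar(x)) return(setNames(integer(0), character(0)))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop(sprintf("malformed composition string: '%s'", x), call. = FALSE)
  k <- as.integer(vapply(kv, `[`, character(1), 1L))
  cnt <- as.integer(vapply(kv, `[`, character(1), 2L))
  if (anyNA(k) || anyNA(cnt) || any(k < 1L) || any(cnt < 0L) ||
      anyDuplicated(k))
    stop(sprintf("malformed composition string: '%s'", x), call. = FALSE)
  ord <- order(k)
  setNames(cnt[ord], k[ord])
}

composition_n_total <- function(x) {
  cc <- parse_composition(x)
  if (!length(cc)) return(0L)
  sum(as.integer(names(cc)) * cc)
}

table_columns <- c("clone_id", "timepoint_days", "composition",
                   "n_total", "m_prog")

#' Read a clone table
#'
#' Reads a cross-sectional clone-observation table (one row per clone per
#' harvest timepoint) from delimited text. Comma/tab delimiter is chosen by
#' extension (`.csv` = comma, anything else = tab). Columns: `clone_id`,
#' `timepoint_days`, `composition` (see [format_composition()]), `n_total`,
#' `m_prog` (may be empty when GFRa1- cells were not scored). Every row is
#' validated: `n_total` must equal the nucleus count implied by the
#' composition string, and timepoints must be >= 0; failures are reported
#' with row numbers. Unknown columns are kept with a warning.
#'
#' @param path Path to the file.
#' @return A validated data frame.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  missing <- setdiff(table_columns, names(tab))
  if (length(missing))
    stop(sprintf("clone table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(tab), table_columns)
  if (length(extra))
    warning(sprintf("unknown column(s) kept as-is: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  tab$timepoint_days <- as.numeric(tab$timepoint_days)
  tab$n_total <- as.integer(tab$n_total)
  tab$m_prog <- suppressWarnings(as.numeric(tab$m_prog))
  validate_clone_table(tab)
  tab
}

validate_clone_table <- function(tab) {
  implied <- vapply(tab$composition, composition_n_total, integer(1),
                    USE.NAMES = FALSE)
  bad <- which(implied != tab$n_total)
  if (length(bad))
    stop(sprintf(
      "n_total does not match composition in row(s): %s (e.g. row %d: composition '%s' implies %d, n_total is %d)",
      paste(bad, collapse = ", "), bad[1], tab$composition[bad[1]],
      implied[bad[1]], tab$n_total[bad[1]]), call. = FALSE)
  neg <- which(tab$timepoint_days < 0 | is.na(tab$timepoint_days))
  if (length(neg))
    stop(sprintf("invalid timepoint_days in row(s): %s",
                 paste(neg, collapse = ", ")), call. = FALSE)
  invisible(tab)
}

#' Write a clone table
#'
#' Writes a clone table in the exchange format of [read_clone_table()];
#' delimiter chosen by extension (`.csv` = comma, otherwise tab).
#'
#' @param tab Clone table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  missing <- setdiff(table_columns, names(tab))
  if (length(missing))
    stop(sprintf("clone table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(tab[, table_columns], path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a model/fit configuration file
#'
#' Reads a YAML (or JSON, by extension) configuration. A `model:` block
#' naming [ssc_params()] fields exactly is converted to an `ssc_params`
#' object; `fit:` and `design:` blocks, when present, are returned as
#' lists for use with [fit_config()] and [study_design()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `model` (an `ssc_params` or `NULL`) and any
#'   further top-level blocks as plain lists.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$model)) {
    known <- names(formals(ssc_params))
    unknown <- setdiff(names(cfg$model), known)
    if (length(unknown))
      stop(sprintf("unknown model field(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    cfg$model <- do.call(ssc_params, cfg$model)
  }
  cfg
}

#' Write a results object as JSON
#'
#' Serializes fits, sensitivity grids or plain lists to JSON, embedding
#' seed and configuration so the output is self-describing and
#' re-runnable.
#'
#' @param x A list-like results object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(prepare_json(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

prepare_json <- function(x) {
  if (inherits(x, "ssc_params") || inherits(x, "ssc_fit") ||
      inherits(x, "ssc_sensitivity"))
    x <- unclass(x)
  if (is.list(x)) return(lapply(x, prepare_json))
  if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
  x
}
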