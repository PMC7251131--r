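#' Read aligned time series from delimited text
#'
#' Reads a CSV/TSV file with one column per variable (optional header and
#' time column) into a tibble of equal-length, finite numeric series. The
#' delimiter is auto-detected between comma and tab from the first line
#' unless forced.
#'
#' @param path File path.
#' @param delim `","`, `"\t"`, or `NULL` to auto-detect.
#' @param time_col Name of a time column to validate (strictly increasing,
#'   uniform step) and keep as `time`; `NULL` if none.
#' @param standardize If `TRUE`, z-score each variable column on ingestion.
#'   The correlation-based indices are affine-invariant, so this is purely a
#'   numerical-conditioning option for series on wildly different scales;
#'   the default leaves data untouched.
#' @return A tibble of numeric columns (plus `time` if requested).
#'   Ragged rows, non-numeric cells, and missing values raise a parse error
#'   naming the offending line.
#' @export
read_timeseries_csv <- function(path, delim = NULL, time_col = NULL,
                                standardize = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("file has no data rows")
  if (is.null(delim)) {
    first <- lines[1]
    delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >
                 lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(fields[[1]])
  p <- length(header)
  for (i in seq_along(fields)[-1]) {
    if (length(fields[[i]]) != p)
      abort(sprintf("ragged row at line %d: %d field(s), expected %d",
                    i, length(fields[[i]]), p))
  }
  body <- matrix(trimws(unlist(fields[-1])), ncol = p, byrow = TRUE)
  # as.numeric goes through strtod, which rounds correctly, so a written
  # %.17g value survives the round trip bit for bit
  out <- as_tibble(setNames(lapply(seq_len(p), function(j) {
    v <- suppressWarnings(as.numeric(body[, j]))
    bad <- which(!is.finite(v))
    if (length(bad))
      abort(sprintf(
        "missing or non-numeric value in column '%s' at line %d (got '%s')",
        header[j], bad[1] + 1, body[bad[1], j]))
    v
  }), header))
  if (!is.null(time_col)) {
    if (!time_col %in% names(out))
      abort(sprintf("time column '%s' not found", time_col))
    tv <- out[[time_col]]
    if (length(tv) > 1 && (any(diff(tv) <= 0) ||
                           max(abs(diff(tv) - diff(tv)[1])) > 1e-8))
      abort(sprintf("time column '%s' is not uniformly increasing", time_col))
    names(out)[names(out) == time_col] <- "time"
    out <- dplyr::relocate(out, "time")
  }
  if (standardize) {
    vcols <- setdiff(names(out), "time")
    out[vcols] <- lapply(out[vcols], function(v) {
      if (sd(v) == 0) abort("cannot standardize a zero-variance column")
      (v - mean(v)) / sd(v)
    })
  }
  out
}

#' Write aligned time series as CSV
#'
#' Full-precision (round-trip exact) CSV writer for simulated or imported
#' series.
#'
#' @param data Data frame of numeric columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(data, path) {
  stopifnot(is.data.frame(data))
  out <- as_tibble(data)[vapply(data, is.numeric, TRUE)]
  # %.17g is the shortest representation guaranteed to round-trip a double
  out[] <- lapply(out, function(col)
    ifelse(col == round(col), as.character(col), sprintf("%.17g", col)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write an inferred edge table as TSV
#'
#' Serialises a [infer_network()] result with a stable column set and a
#' deterministic row order (source, then target), so identical runs produce
#' byte-identical files.
#'
#' @param results A `pcm_network` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(results, path) {
  stopifnot(is.data.frame(results),
            all(c("source", "target", "rho_C", "rho_D", "gamma",
                  "decision") %in% names(results)))
  cols <- c("source", "target", "rho_C", "rho_D", "gamma", "best_delays",
            "p", "q", "decision")
  out <- as_tibble(results)
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA
  out <- dplyr::arrange(out[cols], .data$source, .data$target)
  stopifnot(all(out$decision %in% c("direct", "indirect", "none", "error")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a ground-truth edge list from TSV
#'
#' @param path TSV with columns `source`, `target` (extra columns kept).
#' @return A tibble.
#' @export
read_edge_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("source", "target") %in% names(out)))
    abort("edge table must have 'source' and 'target' columns")
  out
}

#' Serialise / restore a run configuration as JSON
#'
#' A run configuration bundles the I/O fields (input path, variable
#' selection, output directory, log level) with a [pcm_config()]. The JSON
#' round-trip is lossless.
#'
#' @param config A list as returned by [run_config()] or [read_run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  pc <- config$pcm
  if (inherits(pc, "pcm_config")) config$pcm <- unclass(pc)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$pcm)) {
    pc <- raw$pcm
    raw$pcm <- pcm_config(
      dim = pc$dim, lag = pc$lag, delays = pc$delays, k = pc$k,
      exclusion = pc$exclusion, threshold = pc$threshold, order = pc$order,
      surrogates = pc$surrogates, seed = pc$seed,
      conditioning = pc$conditioning, top_q = pc$top_q,
      min_support = pc$min_support, max_chains = pc$max_chains)
  }
  raw
}

#' @rdname write_run_config
#' @param input Input series path.
#' @param variables Character vector of variable columns (NULL = all).
#' @param output_dir Output directory.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @param pcm A [pcm_config()].
#' @export
run_config <- function(input = NULL, variables = NULL, output_dir = ".",
                       log_level = "info", pcm = pcm_config()) {
  stopifnot(inherits(pcm, "pcm_config"))
  list(input = input, variables = variables, output_dir = output_dir,
       log_level = log_level, pcm = pcm)
}
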