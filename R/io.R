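#' Read and write time series files
#'
#' Two formats are supported.  The delimited text format (\code{"csv"} /
#' \code{"tsv"}, autodetected as \code{"auto"}) is one row per node: the
#' first field is the node id and the remaining fields the samples, preceded
#' by a header line \code{# dt=<seconds>} carrying the sampling interval.
#' The binary container (\code{"rds"}) is R's serialization format and
#' round-trips values bit-exactly; it stores shape, \code{dt} and node ids.
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"csv"}, \code{"tsv"} or \code{"rds"}.
#'   \code{"auto"} infers from the file extension.
#' @param dt sampling interval override; required when the text file has no
#'   \code{# dt=} header.
#' @return \code{read_timeseries} returns a \code{\link{ddc_timeseries}};
#'   \code{write_timeseries} invisibly returns \code{path}.
#' @export
read_timeseries <- function(path, format = "auto", dt = NULL) {
  format <- .resolve_format(path, format)
  if (format == "rds") {
    ts <- readRDS(path)
    if (!inherits(ts, "ddc_ts")) stop("`", path, "` does not hold a ddc_ts object")
    return(ts)
  }
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("`", path, "` is empty")
  file_dt <- NULL
  meta <- grep("^#", lines)
  for (i in meta) {
    m <- regmatches(lines[i], regexec("#\\s*dt\\s*=\\s*([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(m) == 2L) file_dt <- as.numeric(m[2])
  }
  if (length(meta)) lines <- lines[-meta]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("`", path, "` has no data rows")
  if (format == "auto" || !any(grepl(sep, lines[1], fixed = TRUE))) {
    # autodetect the delimiter: comma or tab
    sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in `", path, "`: row ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ", widths[1])
  ids <- vapply(fields, `[[`, "", 1L)
  vals <- lapply(fields, function(f) suppressWarnings(as.numeric(f[-1L])))
  for (r in seq_along(vals)) {
    bad <- which(is.na(vals[[r]]))
    if (length(bad))
      stop("non-numeric cell in `", path, "` at row ", r, " (node ", ids[r],
           "), column ", bad[1] + 1L)
  }
  use_dt <- if (!is.null(dt)) dt else file_dt
  if (is.null(use_dt))
    stop("sampling interval missing: `", path,
         "` has no `# dt=` header and no `dt` argument was given")
  ddc_timeseries(do.call(rbind, vals), dt = use_dt, node_ids = ids)
}

#' @param ts a \code{\link{ddc_timeseries}} to write.
#' @param digits significant digits for the text formats (text round trips
#'   are exact to about 1e-15 at the default).
#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path, format = "auto", digits = 17L) {
  .assert_ts(ts)
  format <- .resolve_format(path, format)
  if (format == "rds") {
    saveRDS(ts, path)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g", ts$dt), con)
  for (r in seq_len(nrow(ts$values)))
    writeLines(paste(c(ts$node_ids[r],
                       formatC(ts$values[r, ], format = "g", digits = digits)),
                     collapse = sep), con)
  invisible(path)
}

.resolve_format <- function(path, format) {
  format <- match.arg(format, c("auto", "csv", "tsv", "rds", "binary"))
  if (format == "binary") format <- "rds"
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", rds = "rds",
                     stop("cannot infer format from extension `.", ext,
                          "`; pass `format` explicitly"))
  }
  format
}

#' Read and write spike trains as two-column text
#'
#' The file holds one spike per line: \code{neuron_id<sep>spike_time_s}.
#' Neurons that never fire are preserved through the id set passed in
#' \code{node_ids} (writing records every id in a \code{# neurons=} header).
#'
#' @param path file path.
#' @param duration recording duration in seconds (required when reading a
#'   file without a \code{# duration=} header).
#' @param node_ids optional complete set of neuron ids.
#' @return \code{read_spiketrains} returns a \code{\link{ddc_spiketrains}}.
#' @export
read_spiketrains <- function(path, duration = NULL, node_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines)
  file_dur <- NULL
  for (i in meta) {
    m <- regmatches(lines[i], regexec("#\\s*duration\\s*=\\s*([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(m) == 2L) file_dur <- as.numeric(m[2])
    m <- regmatches(lines[i], regexec("#\\s*neurons\\s*=\\s*(.+)$", lines[i]))[[1]]
    if (length(m) == 2L && is.null(node_ids))
      node_ids <- strsplit(trimws(m[2]), ",", fixed = TRUE)[[1]]
  }
  if (length(meta)) lines <- lines[-meta]
  lines <- lines[nzchar(trimws(lines))]
  dur <- if (!is.null(duration)) duration else file_dur
  if (is.null(dur)) stop("recording `duration` is required")
  if (length(lines)) {
    parts <- strsplit(lines, "[,\t ]+")
    ids <- vapply(parts, `[[`, "", 1L)
    tms <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (anyNA(tms)) stop("non-numeric spike time at line ", which(is.na(tms))[1])
  } else {
    ids <- character(); tms <- numeric()
  }
  if (is.null(node_ids)) node_ids <- unique(ids)
  trains <- lapply(node_ids, function(id) sort(tms[ids == id]))
  names(trains) <- node_ids
  ddc_spiketrains(trains, duration = dur)
}

#' @param spikes a \code{\link{ddc_spiketrains}} to write.
#' @rdname read_spiketrains
#' @export
write_spiketrains <- function(spikes, path) {
  stopifnot(inherits(spikes, "ddc_spikes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration=%.17g", spikes$duration), con)
  writeLines(paste0("# neurons=", paste(names(spikes$spike_times), collapse = ",")), con)
  for (id in names(spikes$spike_times)) {
    tk <- spikes$spike_times[[id]]
    if (length(tk))
      writeLines(sprintf("%s,%.17g", id, tk), con)
  }
  invisible(path)
}

#' Write or read a connectivity estimate with its JSON sidecar
#'
#' The matrix is stored as a delimited square matrix with node-id headers;
#' the estimator identity and its parameters go to \code{<path>.json}.
#'
#' @param est a \code{\link{ddc_estimate}}.
#' @param path path of the matrix file (CSV).
#' @return \code{read_estimate} returns a \code{ddc_estimate}.
#' @export
write_estimate <- function(est, path) {
  stopifnot(inherits(est, "ddc_estimate"))
  m <- est$matrix
  dimnames(m) <- list(est$node_ids, est$node_ids)
  utils::write.csv(m, path, row.names = TRUE)
  sidecar <- list(estimator = est$estimator,
                  params = if (length(est$params)) est$params else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_estimate
#' @export
read_estimate <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(estimator = "unknown", params = list())
  new_ddc_estimate(m, estimator = meta$estimator,
                   params = as.list(meta$params), node_ids = rownames(m))
}

#' Write or read a ground-truth graph as a delimited matrix
#' @param g a \code{\link{ddc_network}}.
#' @param path CSV path.
#' @export
write_network <- function(g, path) {
  stopifnot(inherits(g, "ddc_network"))
  utils::write.csv(g$W, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  ddc_network(as.matrix(utils::read.csv(path, check.names = FALSE)))
}
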