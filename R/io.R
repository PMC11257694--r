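# Delimited-text readers/writers for timeseries, networks, partitions and
# node tables. Delimiters are auto-detected among tab and comma; writers
# default to tab. All round-trips preserve values to full precision.

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a region timeseries from delimited text
#'
#' Expected layout: rows are timepoints, columns are regions, first row
#' holds region labels; delimiter tab or comma (auto-detected). With
#' `regions_as_rows = TRUE` the file is read transposed (first column holds
#' region labels). A file with more columns than rows triggers a warning
#' suggesting the transposed layout. Ragged rows, non-numeric cells and
#' duplicate region labels are reported with their location.
#'
#' @param path File path.
#' @param regions_as_rows Set when rows are regions rather than timepoints.
#' @return A numeric matrix, timepoints x regions.
#' @export
read_timeseries <- function(path, regions_as_rows = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delim <- detect_delim(path)
  nf <- utils::count.fields(path, sep = delim, quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])
    stop("ragged rows at line(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df <- utils::read.table(path, header = !regions_as_rows, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (regions_as_rows) {
    labels <- as.character(df[[1]])
    vals <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(vals) <- labels
    rownames(vals) <- NULL
    df <- as.data.frame(vals, check.names = FALSE)
  }
  labels <- colnames(df)
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0) {
    stop("duplicate region label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  non_num <- !vapply(df, is.numeric, TRUE)
  if (any(non_num)) {
    for (cn in labels[non_num]) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))
      stop("non-numeric cell(s) in column '", cn, "' at data line(s) ",
           paste(utils::head(bad_rows, 5), collapse = ", "), call. = FALSE)
    }
  }
  m <- as.matrix(df)
  if (!regions_as_rows && ncol(m) > nrow(m)) {
    warning("file has more columns (", ncol(m), ") than rows (", nrow(m),
            "); if rows are regions, re-read with regions_as_rows = TRUE",
            call. = FALSE)
  }
  m
}

#' Write a region timeseries as delimited text
#'
#' Inverse of [read_timeseries()]: rows are timepoints, columns regions,
#' header row of region labels.
#'
#' @param ts Timepoints x regions matrix with region column names.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @export
write_timeseries <- function(ts, path, delim = "\t") {
  stopifnot(is.matrix(ts))
  utils::write.table(ts, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read an information network matrix
#'
#' Square matrix with region labels as both header row and first column.
#' `write_network()` also drops a JSON provenance sidecar
#' (`<path>.json`: measure, tau, units, n_samples_used, plus any extra
#' fields) unless `sidecar = FALSE`.
#'
#' @param network An `info_network`.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @param sidecar Write the JSON provenance sidecar (default TRUE).
#' @param extra Named list merged into the sidecar.
#' @export
write_network <- function(network, path, delim = "\t", sidecar = TRUE,
                          extra = list()) {
  stopifnot(inherits(network, "info_network"))
  df <- data.frame(region = network$region_ids, network$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (sidecar) {
    prov <- c(list(measure = network$measure, tau = network$tau,
                   units = "nats",
                   n_samples_used = network$n_samples_used,
                   tool = paste0("phidnet ",
                                 as.character(utils::packageVersion("phidnet")))),
              extra)
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_network
#' @param measure,tau Metadata for the returned `info_network` when no
#'   sidecar is present.
#' @export
read_network <- function(path, measure = NULL, tau = NULL) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  side <- paste0(path, ".json")
  n_used <- NA_integer_
  if (file.exists(side)) {
    prov <- jsonlite::read_json(side, simplifyVector = TRUE)
    measure <- measure %||% prov$measure
    tau <- tau %||% prov$tau
    n_used <- prov$n_samples_used %||% NA_integer_
  }
  new_info_network(vals, measure %||% "unknown", ids, tau %||% 1L, n_used)
}

#' Read / write a module partition
#'
#' Two-column delimited text: region id, module label.
#'
#' @param path File path.
#' @return A tibble with columns `region` and `module`.
#' @export
read_partition <- function(path) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2)
  tibble::tibble(region = as.character(df[[1]]),
                 module = as.character(df[[2]]))
}

#' @rdname read_partition
#' @param partition Tibble with columns `region`, `module`.
#' @param delim Field delimiter (default tab).
#' @export
write_partition <- function(partition, path, delim = "\t") {
  utils::write.table(partition[, c("region", "module")], path, sep = delim,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a node profile table
#'
#' Tab-separated per-region table (strengths, ranks, gradient, workspace
#' flag and, when present, participation coefficients and roles).
#'
#' @param profiles Tibble from [node_profiles()].
#' @param path Output path.
#' @export
write_node_table <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a significant-edge list
#'
#' @param edges Edge tibble (e.g. `nbs_result$edges`).
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
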