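#' Read a delimited time-series matrix
#'
#' Reads a rectangular numeric table (rows = samples, columns = channels;
#' comma, tab or semicolon separated, auto-detected) with an optional
#' header row of channel labels, into a [ts_set()].
#'
#' @param path file path.
#' @param fs sampling rate in Hz to attach (default 1).
#' @return A `ts_set` with channels taken from the columns.
#' @export
read_timeseries_csv <- function(path, fs = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stop_bayesconn("empty_input", sprintf("empty input file: %s", path))
  sep <- detect_sep(lines[[1]])
  toks <- strsplit(lines, sep)
  first <- trimws(toks[[1]])
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  labels <- if (has_header) first else NULL
  data_tok <- if (has_header) toks[-1] else toks
  if (length(data_tok) == 0)
    stop_bayesconn("empty_input",
                   sprintf("no data rows in input file: %s", path))
  ncols <- length(first)
  vals <- matrix(NA_real_, length(data_tok), ncols)
  for (i in seq_along(data_tok)) {
    row <- trimws(data_tok[[i]])
    lineno <- i + has_header
    if (length(row) != ncols)
      stop_bayesconn("format", sprintf(
        "ragged row at line %d of %s: %d fields, expected %d", lineno,
        path, length(row), ncols))
    num <- suppressWarnings(as.numeric(row))
    if (any(is.na(num)))
      stop_bayesconn("parse", sprintf(
        "non-numeric cell at line %d of %s: '%s'", lineno, path,
        row[which(is.na(num))[1]]))
    vals[i, ] <- num
  }
  ts_set(t(vals), fs = fs, labels = labels)
}

detect_sep <- function(line) {
  for (s in c(",", "\t", ";")) if (grepl(s, line, fixed = TRUE)) return(s)
  "[[:space:]]+"
}

#' Write a time-series set as delimited text
#'
#' Writes samples as rows and channels as columns, with a header of
#' channel labels, at 15 significant digits (round-trip safe well beyond
#' 12 digits).
#'
#' @param ts a [ts_set()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @export
write_timeseries_csv <- function(ts, path, sep = ",") {
  stopifnot(inherits(ts, "ts_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ts$labels, collapse = sep), con)
  m <- t(ts$values)
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(m[i, ], digits = 15, format = "g"),
                     collapse = sep), con)
  invisible(path)
}

#' Read a single UCI EEG Database trial
#'
#' Parses the long trial format of the UCI EEG Database: comment lines
#' starting with `#`, then one record per line of the form
#' `channel-name epoch value`, 256 epochs (one second at 256 Hz) for each
#' of the 64 electrodes.
#'
#' @param path file path.
#' @param fs sampling rate (fixed at 256 Hz for this archive).
#' @return A `ts_set` with electrode labels.
#' @export
read_uci_eeg_trial <- function(path, fs = 256) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  data <- lines[!startsWith(trimws(lines), "#")]
  if (length(data) == 0)
    stop_bayesconn("empty_input",
                   sprintf("no data records in trial file: %s", path))
  toks <- strsplit(trimws(data), "[[:space:]]+")
  bad <- which(lengths(toks) != 3)
  if (length(bad) > 0)
    stop_bayesconn("format", sprintf(
      "malformed record in %s (expected 'channel epoch value'): '%s'",
      path, data[bad[1]]))
  chan <- vapply(toks, `[[`, character(1), 1L)
  epoch <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1),
                                              2L)))
  value <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1),
                                              3L)))
  if (any(is.na(epoch)) || any(is.na(value)))
    stop_bayesconn("parse", sprintf("non-numeric epoch or value in %s",
                                    path))
  channels <- unique(chan)
  t_len <- max(epoch) + 1L
  counts <- table(factor(chan, levels = channels))
  incomplete <- counts != t_len
  if (any(incomplete))
    stop_bayesconn("incomplete_trial", paste0(
      "incomplete trial ", path, ": ",
      paste(sprintf("%s has %d of %d epochs",
                    names(counts)[incomplete], as.integer(counts[incomplete]),
                    t_len), collapse = "; ")))
  vals <- matrix(NA_real_, length(channels), t_len)
  vals[cbind(match(chan, channels), epoch + 1L)] <- value
  if (any(is.na(vals)))
    stop_bayesconn("incomplete_trial",
                   sprintf("missing epochs in trial file %s", path))
  ts_set(vals, fs = fs, labels = channels)
}

#' Write and read binary networks
#'
#' `write_network()` serialises a `binary_network` either as an undirected
#' edge list (tab-separated `i j`, 0-based node ids, i < j) or as a dense
#' 0/1 matrix; `read_network()` reads it back bit-exactly.
#'
#' @param net a `binary_network`.
#' @param path file path.
#' @param format `"edgelist"` or `"matrix"`.
#' @param n_nodes node count, required to read an edge list (isolated
#'   nodes carry no records).
#' @return `read_network()` returns a `binary_network`.
#' @export
write_network <- function(net, path, format = c("edgelist", "matrix")) {
  format <- match.arg(format)
  net <- binary_network(net)
  if (format == "matrix") {
    write.table(unclass(net), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    idx <- upper_pairs(nrow(net))
    on_ <- unclass(net)[idx] != 0
    df <- data.frame(i = idx[on_, 1] - 1L, j = idx[on_, 2] - 1L)
    df <- df[order(df$i, df$j), , drop = FALSE]
    con <- file(path, "w")
    writeLines(sprintf("%d\t%d", df$i, df$j), con)
    close(con)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "matrix"),
                         n_nodes = NULL) {
  format <- match.arg(format)
  if (format == "matrix") {
    m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    return(binary_network(m))
  }
  stopifnot(!is.null(n_nodes))
  A <- matrix(0L, n_nodes, n_nodes)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0) {
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    ij <- vapply(toks, function(t) as.integer(t[1:2]), integer(2)) + 1L
    A[t(ij)] <- 1L
    A[t(ij[2:1, , drop = FALSE])] <- 1L
  }
  binary_network(A)
}

#' Write a network ensemble to a directory
#'
#' One edge-list file per member plus a JSON manifest recording method,
#' seed, count, density and node count — enough to re-create the run.
#'
#' @param ensemble a `network_ensemble`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "network_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ensemble$networks)) {
    write_network(ensemble$networks[[i]],
                  file.path(dir, sprintf("member_%05d.tsv", i)))
  }
  manifest <- list(
    generator = "bayesconn", method = ensemble$method, seed = ensemble$seed,
    count = ensemble$count, density = ensemble$density,
    n_nodes = ensemble$n_nodes)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
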