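# Registry of logger-file dialects. Vendors change export layouts without
# notice, so the set is extensible: two exemplar dialects ship built in
# (a wide single-node "tower logger" export and a long multi-node
# "wireless" export) and new ones can be registered at run time.

.dialects <- new.env(parent = emptyenv())

#' Define a logger dialect
#'
#' A dialect describes one concrete data-logger export layout: delimiter,
#' header size, timestamp format, column layout and the sentinel strings
#' the logger writes for missing values.
#'
#' @param name Unique dialect name.
#' @param delimiter Single-character field delimiter.
#' @param n_header_lines Number of header lines before data records.
#' @param ts_format `strptime` format of the timestamp field.
#' @param layout `"wide"` (one column per channel, single node per file)
#'   or `"long"` (timestamp, node_id, channel, value columns).
#' @param channels Allowed channels (ordered); for wide layouts the
#'   header names a subset of these.
#' @param na_sentinels Strings the logger writes for missing readings.
#' @return A `logger_dialect` object.
#' @export
logger_dialect <- function(name, delimiter, n_header_lines, ts_format,
                           layout = c("wide", "long"),
                           channels = CHANNELS,
                           na_sentinels = c("-9999", "NAN", "NaN")) {
  layout <- match.arg(layout)
  if (length(channels) == 0) abort("`channels` must be non-empty.")
  if (any(na_sentinels %in% as.character(channels)))
    abort("Missing-value sentinels must be distinct from channel names.")
  if (!all(is.na(suppressWarnings(as.numeric(na_sentinels)))) &&
      any(!is.na(suppressWarnings(as.numeric(na_sentinels))) &
          !(na_sentinels %in% c("-9999"))))
    abort("Sentinels other than -9999 must not parse as ordinary numbers.")
  structure(list(name = name, delimiter = delimiter,
                 n_header_lines = as.integer(n_header_lines),
                 ts_format = ts_format, layout = layout,
                 channels = channels, na_sentinels = na_sentinels),
            class = "logger_dialect")
}

#' @export
print.logger_dialect <- function(x, ...) {
  cat(sprintf("<logger_dialect> %s: %s layout, delim %s, %d header line(s)\n",
              x$name, x$layout, dQuote(x$delimiter), x$n_header_lines))
  invisible(x)
}

#' Register a logger dialect
#'
#' Adds a dialect to the registry consulted by [sniff_format()],
#' [parse_logger_file()] and [write_logger_file()].
#'
#' @param dialect A [logger_dialect()].
#' @param overwrite Replace an existing dialect of the same name?
#' @return The dialect, invisibly.
#' @export
register_dialect <- function(dialect, overwrite = FALSE) {
  stopifnot(inherits(dialect, "logger_dialect"))
  if (!overwrite && dialect$name %in% ls(.dialects))
    abort(sprintf("Dialect '%s' is already registered.", dialect$name))
  assign(dialect$name, dialect, envir = .dialects)
  invisible(dialect)
}

#' List registered dialect names
#' @return Character vector of dialect names.
#' @export
list_dialects <- function() sort(ls(.dialects))

get_dialect <- function(dialect) {
  if (inherits(dialect, "logger_dialect")) return(dialect)
  if (!dialect %in% ls(.dialects))
    abort(sprintf("Unknown dialect '%s'. Registered dialects: %s.",
                  dialect, paste(list_dialects(), collapse = ", ")),
          class = "phenosense_unknown_dialect")
  get(dialect, envir = .dialects)
}

register_builtin_dialects <- function() {
  register_dialect(logger_dialect(
    name = "tower_wide", delimiter = ",", n_header_lines = 2,
    ts_format = "%Y-%m-%d %H:%M:%S", layout = "wide",
    channels = CHANNELS, na_sentinels = c("-9999", "NAN")
  ), overwrite = TRUE)
  register_dialect(logger_dialect(
    name = "wireless_long", delimiter = "\t", n_header_lines = 1,
    ts_format = "%m/%d/%Y %H:%M", layout = "long",
    channels = CHANNELS, na_sentinels = c("NaN", "-9999")
  ), overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_dialects()
}

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 12)
  gsub(" ", "", out)
}

#' Write a series table as a logger file
#'
#' Serialises a [series_table()] in a registered dialect, optionally
#' injecting structural corruptions of the kinds real loggers produce
#' (extra columns, missing columns, garbled fields) so that ingestion
#' defect reporting can be tested against known ground truth.
#'
#' @param table A `series_table`. Wide dialects accept a single node only.
#' @param dialect Dialect name or [logger_dialect()] object.
#' @param path Output file path.
#' @param corruption_rate Fraction of data records to corrupt, in \[0, 1\].
#' @param seed Optional integer seed making the corruption draw
#'   reproducible; the session RNG state is left untouched.
#' @return Invisibly, a list with `path`, `n_records`, and `corrupted`
#'   (tibble of record index and corruption kind; the ground truth).
#' @export
write_logger_file <- function(table, dialect, path,
                              corruption_rate = 0, seed = NULL) {
  d <- get_dialect(dialect)
  stopifnot(inherits(table, "series_table"))
  if (corruption_rate < 0 || corruption_rate > 1)
    abort("`corruption_rate` must be in [0, 1].")

  if (d$layout == "wide") {
    nodes <- unique(table$node_id)
    if (length(nodes) > 1)
      abort(sprintf("Wide dialect '%s' holds one node per file; got %d nodes.",
                    d$name, length(nodes)))
    node <- if (length(nodes) == 1) nodes else "tower"
    chans <- intersect(d$channels, unique(table$channel))
    wide <- tidyr::pivot_wider(
      as_tibble(table)[c("timestamp", "channel", "value")],
      names_from = "channel", values_from = "value")
    wide <- dplyr::arrange(wide, .data$timestamp)
    header <- c(sprintf("# logger export; node=%s", node),
                paste(c("timestamp", chans), collapse = d$delimiter))
    lines <- vapply(seq_len(nrow(wide)), function(i) {
      vals <- vapply(chans, function(ch) {
        v <- wide[[ch]][i]
        if (is.na(v)) d$na_sentinels[1] else fmt_num(v)
      }, character(1))
      paste(c(format(wide$timestamp[i], d$ts_format), vals),
            collapse = d$delimiter)
    }, character(1))
  } else {
    tb <- dplyr::arrange(as_tibble(table), .data$node_id, .data$channel,
                         .data$timestamp)
    header <- paste(c("timestamp", "node_id", "channel", "value"),
                    collapse = d$delimiter)
    lines <- paste(format(tb$timestamp, d$ts_format), tb$node_id, tb$channel,
                   ifelse(is.na(tb$value), d$na_sentinels[1],
                          fmt_num(tb$value)),
                   sep = d$delimiter)
  }

  n <- length(lines)
  corrupted <- tibble(record = integer(), kind = character())
  if (corruption_rate > 0 && n > 0) {
    draw <- function() {
      idx <- which(stats::runif(n) < corruption_rate)
      kinds <- sample(c("extra_column", "missing_column", "garbled"),
                      length(idx), replace = TRUE)
      list(idx = idx, kinds = kinds)
    }
    cr <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    for (j in seq_along(cr$idx)) {
      i <- cr$idx[j]
      fields <- strsplit(lines[i], d$delimiter, fixed = TRUE)[[1]]
      fields <- switch(cr$kinds[j],
        extra_column = c(fields, "999"),
        missing_column = fields[-length(fields)],
        garbled = { fields[length(fields)] <- "#ERR#"; fields })
      lines[i] <- paste(fields, collapse = d$delimiter)
    }
    corrupted <- tibble(record = cr$idx, kind = cr$kinds)
  }

  writeLines(c(header, lines), path)
  invisible(list(path = path, n_records = n, corrupted = corrupted))
}
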