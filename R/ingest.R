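# Ingestion: parse heterogeneous logger exports into the canonical
# series_table, quarantining (never repairing) malformed records and
# reporting every defect with its record index, so problems are visible
# before the data enters analysis.

read_logger_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

# Run the structural checks of one dialect against header + first data
# records; returns character vector of failure descriptions (empty = pass).
dialect_check <- function(d, lines) {
  fails <- character()
  if (length(lines) <= d$n_header_lines)
    return("no data records")
  header <- lines[seq_len(d$n_header_lines)]
  if (d$layout == "wide") {
    if (!grepl("^#", header[1]))
      fails <- c(fails, "first header line does not start with '#'")
    cols <- strsplit(header[d$n_header_lines], d$delimiter, fixed = TRUE)[[1]]
    if (length(cols) < 2 || cols[1] != "timestamp")
      fails <- c(fails, "column header does not start with 'timestamp'")
    else if (!all(cols[-1] %in% d$channels))
      fails <- c(fails, sprintf("unknown channel column(s): %s",
                                paste(setdiff(cols[-1], d$channels),
                                      collapse = ", ")))
    expected_n <- length(cols)
  } else {
    cols <- strsplit(header[1], d$delimiter, fixed = TRUE)[[1]]
    if (!identical(cols, c("timestamp", "node_id", "channel", "value")))
      fails <- c(fails, "header is not 'timestamp, node_id, channel, value'")
    expected_n <- 4L
  }
  first_data <- lines[d$n_header_lines + 1]
  fields <- strsplit(first_data, d$delimiter, fixed = TRUE)[[1]]
  if (length(fields) != expected_n)
    fails <- c(fails, sprintf("first data record has %d fields, expected %d",
                              length(fields), expected_n))
  else if (is.na(ps_time(fields[1], d$ts_format)))
    fails <- c(fails, "first data record's timestamp does not parse")
  fails
}

#' Detect the dialect of a logger file
#'
#' Tests the file's header and first data record against every registered
#' dialect. Exactly one consistent dialect is returned; zero or several
#' consistent dialects raise an explicit error (the function never
#' guesses), listing which check failed for each near-miss.
#'
#' @param path Path to a logger export.
#' @return The matching [logger_dialect()].
#' @export
sniff_format <- function(path) {
  lines <- read_logger_lines(path)
  names <- list_dialects()
  results <- lapply(names, function(nm) dialect_check(get_dialect(nm), lines))
  names(results) <- names
  ok <- names[vapply(results, length, integer(1)) == 0]
  if (length(ok) == 1) return(get_dialect(ok))
  detail <- vapply(names, function(nm) {
    f <- results[[nm]]
    sprintf("  %s: %s", nm, if (length(f) == 0) "consistent"
            else paste(f, collapse = "; "))
  }, character(1))
  if (length(ok) == 0)
    abort(paste0("No registered dialect matches '", basename(path), "':\n",
                 paste(detail, collapse = "\n")),
          class = "phenosense_no_dialect")
  abort(paste0("Ambiguous format: dialects ", paste(ok, collapse = ", "),
               " are all consistent with '", basename(path), "':\n",
               paste(detail, collapse = "\n")),
        class = "phenosense_ambiguous_dialect")
}

new_ingestion_report <- function(source, dialect, user, options,
                                 counts, defects) {
  structure(list(source = source, dialect = dialect,
                 ingested_at = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 user = user, options = options,
                 counts = counts, defects = defects),
            class = "ingestion_report")
}

#' @export
print.ingestion_report <- function(x, ...) {
  cat(sprintf("<ingestion_report> %s (dialect %s)\n", x$source, x$dialect))
  cat(sprintf("  ingested %s by %s\n", x$ingested_at, x$user))
  cat(sprintf("  records: %d total, %d accepted, %d malformed\n",
              x$counts[["total"]], x$counts[["accepted"]],
              x$counts[["malformed"]]))
  if (nrow(x$defects) > 0) {
    cat("  defects:\n")
    for (i in seq_len(min(nrow(x$defects), 10)))
      cat(sprintf("    record %d: %s\n", x$defects$record[i],
                  x$defects$message[i]))
    if (nrow(x$defects) > 10)
      cat(sprintf("    ... and %d more\n", nrow(x$defects) - 10))
  }
  invisible(x)
}

#' Parse a logger file into a series table
#'
#' Every physical data record is classified: well-formed records enter the
#' returned [series_table()] flagged `ok` (missing-value sentinels become
#' explicit `gap` records); records with the wrong column count,
#' unparseable fields, unknown channels or a timestamp running backwards
#' are quarantined and appear only in the report, each with its record
#' index and a message naming the cause. Parsing is total: no input file
#' raises an unhandled failure — the worst case is an all-quarantined
#' report. Accepted + quarantined always equals the physical record count.
#'
#' @param path Path to the logger export.
#' @param dialect Dialect name, [logger_dialect()], or `"auto"` to
#'   [sniff_format()] first.
#' @param user Agent string recorded in the report's provenance.
#' @return A list with elements `table` (a `series_table`, provenance
#'   attached) and `report` (an `ingestion_report`).
#' @export
parse_logger_file <- function(path, dialect = "auto",
                              user = Sys.info()[["user"]]) {
  d <- if (identical(dialect, "auto")) sniff_format(path) else
    get_dialect(dialect)
  lines <- read_logger_lines(path)
  data_lines <- if (length(lines) > d$n_header_lines)
    lines[-seq_len(d$n_header_lines)] else character()
  n <- length(data_lines)

  if (d$layout == "wide") {
    header_cols <- strsplit(lines[d$n_header_lines], d$delimiter,
                            fixed = TRUE)[[1]]
    chans <- header_cols[-1]
    node <- sub(".*node=", "", lines[1])
    if (identical(node, lines[1])) node <- "node1"
    expected_n <- 1L + length(chans)
  } else {
    expected_n <- 4L
  }

  defects <- list()
  rows <- vector("list", n)
  last_ts <- new.env(parent = emptyenv())  # per (node|channel) running max

  quarantine <- function(i, kind, msg) {
    defects[[length(defects) + 1]] <<- tibble(record = i, kind = kind,
                                              message = msg)
  }

  for (i in seq_len(n)) {
    fields <- strsplit(data_lines[i], d$delimiter, fixed = TRUE)[[1]]
    if (length(fields) != expected_n) {
      kind <- if (length(fields) > expected_n) "extra_column" else
        "missing_column"
      quarantine(i, kind, sprintf(
        "record %d has %s column(s): %d fields, expected %d", i,
        if (kind == "extra_column") "extra" else "missing",
        length(fields), expected_n))
      next
    }
    ts <- ps_time(fields[1], d$ts_format)
    if (is.na(ts)) {
      quarantine(i, "bad_timestamp",
                 sprintf("record %d: unparseable timestamp '%s'", i, fields[1]))
      next
    }
    if (d$layout == "wide") {
      raw <- fields[-1]
      is_gap <- raw %in% d$na_sentinels
      vals <- suppressWarnings(as.numeric(raw))
      bad <- !is_gap & is.na(vals)
      if (any(bad)) {
        quarantine(i, "bad_value", sprintf(
          "record %d: unparseable value '%s' in channel %s", i,
          raw[which(bad)[1]], chans[which(bad)[1]]))
        next
      }
      key <- node
      prev <- if (exists(key, last_ts)) get(key, last_ts) else NULL
      if (!is.null(prev) && ts <= prev) {
        quarantine(i, "timestamp_regression", sprintf(
          "record %d: timestamp %s does not advance past %s", i,
          format(ts), format(prev)))
        next
      }
      assign(key, ts, last_ts)
      vals[is_gap] <- NA_real_
      rows[[i]] <- tibble(timestamp = ts, node_id = node, channel = chans,
                          value = vals,
                          flag = ifelse(is_gap, "gap", "ok"))
    } else {
      chan <- fields[3]
      if (!chan %in% d$channels) {
        quarantine(i, "unknown_channel",
                   sprintf("record %d: unknown channel '%s'", i, chan))
        next
      }
      raw <- fields[4]
      is_gap <- raw %in% d$na_sentinels
      val <- suppressWarnings(as.numeric(raw))
      if (!is_gap && is.na(val)) {
        quarantine(i, "bad_value",
                   sprintf("record %d: unparseable value '%s'", i, raw))
        next
      }
      key <- paste(fields[2], chan, sep = "\r")
      prev <- if (exists(key, last_ts)) get(key, last_ts) else NULL
      if (!is.null(prev) && ts <= prev) {
        quarantine(i, "timestamp_regression", sprintf(
          "record %d: timestamp %s does not advance past %s", i,
          format(ts), format(prev)))
        next
      }
      assign(key, ts, last_ts)
      rows[[i]] <- tibble(timestamp = ts, node_id = fields[2], channel = chan,
                          value = if (is_gap) NA_real_ else val,
                          flag = if (is_gap) "gap" else "ok")
    }
  }

  accepted_rows <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  defects <- if (length(defects) > 0) dplyr::bind_rows(defects) else
    tibble(record = integer(), kind = character(), message = character())
  n_accepted <- sum(!vapply(rows, is.null, logical(1)))
  counts <- c(total = n, accepted = n_accepted,
              malformed = n - n_accepted, out_of_range = 0L)

  report <- new_ingestion_report(
    source = path, dialect = d$name, user = user,
    options = list(dialect = d$name),
    counts = counts, defects = defects)

  tb <- if (nrow(accepted_rows) == 0) series_table() else {
    tb0 <- dplyr::arrange(accepted_rows, .data$node_id, .data$channel,
                          .data$timestamp)
    validate_series_table(tb0)
    new_series_table(tb0)
  }
  tb <- add_provenance(tb, list(
    action = "ingest", source = path, dialect = d$name, user = user,
    total = n, accepted = n_accepted, malformed = n - n_accepted))
  list(table = tb, report = report)
}

#' Merge series tables
#'
#' Unions the records of several tables into one. Duplicate
#' (timestamp, node, channel) keys are resolved deterministically: the
#' record from the earlier-ingested table (earlier in the argument list)
#' wins, and every conflict is reported in the `conflicts` attribute —
#' values are never silently averaged.
#'
#' @param tables A list of `series_table` objects.
#' @return A merged `series_table`; `attr(, "conflicts")` holds a tibble
#'   of the losing duplicate records, and provenance is concatenated.
#' @export
merge_tables <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  for (t in tables) stopifnot(inherits(t, "series_table"))
  all_prov <- unlist(lapply(tables, provenance), recursive = FALSE)
  stacked <- dplyr::bind_rows(lapply(seq_along(tables), function(i)
    dplyr::mutate(as_tibble(tables[[i]]), .origin = i)))
  if (nrow(stacked) == 0) {
    out <- new_series_table(stacked[c("timestamp", "node_id", "channel",
                                      "value", "flag")],
                            provenance = all_prov)
    attr(out, "conflicts") <- stacked[0, ]
    return(out)
  }
  stacked <- dplyr::arrange(stacked, .data$.origin)
  dup <- duplicated(stacked[c("timestamp", "node_id", "channel")])
  conflicts <- stacked[dup, ]
  kept <- stacked[!dup, ]
  if (nrow(conflicts) > 0)
    rlang::inform(sprintf(
      "merge_tables: %d duplicate key(s) resolved first-wins; see attr(, 'conflicts').",
      nrow(conflicts)))
  out <- dplyr::arrange(kept[c("timestamp", "node_id", "channel",
                               "value", "flag")],
                        .data$node_id, .data$channel, .data$timestamp)
  out <- new_series_table(out, provenance = all_prov)
  out <- add_provenance(out, list(action = "merge",
                                  n_tables = length(tables),
                                  n_conflicts = nrow(conflicts)))
  attr(out, "conflicts") <- conflicts
  out
}
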