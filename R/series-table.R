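#' Site location
#'
#' Describes where a deployment sits on the globe. All timestamps in this
#' package are interpreted as *local standard time* for the site: field
#' equipment is configured with daylight-saving changes disabled, so the
#' library never applies DST either. Internally timestamps are stored as
#' POSIXct in the "UTC" zone purely so that R cannot apply any DST rule;
#' the clock value is the local standard clock value.
#'
#' @param latitude Degrees north, in \[-90, 90\].
#' @param longitude Degrees east, in \[-180, 180\].
#' @param utc_offset_hours Signed offset of local *standard* time from UTC,
#'   whole hours in \[-12, 14\].
#' @return A `site_location` object.
#' @export
#' @examples
#' site_location(10.5, -85.4, -6) # a Central American dry-forest site
site_location <- function(latitude, longitude, utc_offset_hours) {
  if (!is.numeric(latitude) || latitude < -90 || latitude > 90)
    abort("`latitude` must be in [-90, 90] degrees.")
  if (!is.numeric(longitude) || longitude < -180 || longitude > 180)
    abort("`longitude` must be in [-180, 180] degrees.")
  if (!is.numeric(utc_offset_hours) || utc_offset_hours < -12 ||
      utc_offset_hours > 14 || utc_offset_hours != round(utc_offset_hours))
    abort("`utc_offset_hours` must be a whole number of hours in [-12, 14].")
  structure(
    list(latitude = as.numeric(latitude), longitude = as.numeric(longitude),
         utc_offset_hours = as.integer(utc_offset_hours)),
    class = "site_location"
  )
}

#' @export
print.site_location <- function(x, ...) {
  cat(sprintf("<site_location> lat %.4f, lon %.4f, UTC%+d (local standard time)\n",
              x$latitude, x$longitude, x$utc_offset_hours))
  invisible(x)
}

# Parse a clock time in local standard time into the internal POSIXct
# representation (UTC zone, so no DST rule can ever fire).
ps_time <- function(x, format = "%Y-%m-%d %H:%M:%S") {
  as.POSIXct(x, tz = "UTC", format = format)
}

ps_date <- function(x) as.Date(x, tz = "UTC")

# Minutes since local midnight for a timestamp vector.
clock_minutes <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Construct a series table
#'
#' The universal long-form representation of sensor records after
#' ingestion: one row per (timestamp, node, channel) observation, each row
#' carrying exactly one quality flag. Timestamps are local standard time
#' (see [site_location()]).
#'
#' @param timestamp POSIXct (or parseable character) timestamps, local
#'   standard time, stamped at the *start* of each sampling interval.
#' @param node_id Character node identifiers.
#' @param channel Channel names from [channel_vocabulary()].
#' @param value Numeric readings in the channel's fixed unit; `NA` for gaps.
#' @param flag Quality flag, one of `ok`, `out_of_range`, `malformed`,
#'   `gap`, `failed_sensor`.
#' @return A tibble of class `series_table`, sorted by node, channel, time.
#' @export
series_table <- function(timestamp = as.POSIXct(character(), tz = "UTC"),
                         node_id = character(),
                         channel = character(),
                         value = numeric(),
                         flag = character()) {
  if (is.character(timestamp)) timestamp <- ps_time(timestamp)
  if (length(flag) == 0 && length(timestamp) > 0)
    flag <- rep("ok", length(timestamp))
  tb <- tibble(timestamp = timestamp, node_id = as.character(node_id),
               channel = as.character(channel), value = as.numeric(value),
               flag = as.character(flag))
  validate_series_table(tb)
  new_series_table(dplyr::arrange(tb, .data$node_id, .data$channel, .data$timestamp))
}

new_series_table <- function(tb, provenance = list()) {
  class(tb) <- unique(c("series_table", class(tb)))
  attr(tb, "provenance") <- provenance
  tb
}

validate_series_table <- function(tb) {
  bad_chan <- setdiff(unique(tb$channel), CHANNELS)
  if (length(bad_chan) > 0)
    abort(paste0("Unknown channel(s): ", paste(bad_chan, collapse = ", "),
                 ". Known channels: ", paste(CHANNELS, collapse = ", "), "."))
  bad_flag <- setdiff(unique(tb$flag), FLAGS)
  if (length(bad_flag) > 0)
    abort(paste0("Unknown flag(s): ", paste(bad_flag, collapse = ", "), "."))
  dup <- duplicated(tb[c("timestamp", "node_id", "channel")])
  if (any(dup))
    abort(sprintf("Duplicate (timestamp, node, channel) keys in series table (%d).",
                  sum(dup)))
  invisible(tb)
}

# dplyr verbs strip custom classes; restore after manipulation.
restore_series <- function(tb, template) {
  new_series_table(as_tibble(tb), provenance = attr(template, "provenance"))
}

#' @export
print.series_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<series_table> %d records, %d node(s), channels: %s\n",
              nrow(x), length(unique(x$node_id)),
              paste(sort(unique(x$channel)), collapse = ", ")))
  if (nrow(x) > 0)
    cat(sprintf("  span %s .. %s (local standard time)\n",
                format(min(x$timestamp)), format(max(x$timestamp))))
  if (length(prov) > 0)
    cat(sprintf("  provenance: %d entr%s\n", length(prov),
                if (length(prov) == 1) "y" else "ies"))
  NextMethod()
}

# Append a provenance entry (a named list) to a series table.
add_provenance <- function(tb, entry) {
  prov <- attr(tb, "provenance")
  entry$at <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  attr(tb, "provenance") <- c(prov, list(entry))
  tb
}

#' Provenance trail of a series table
#'
#' Every ingestion, correction and filter appends an entry describing what
#' was done, so any table can be traced back to its source files and the
#' options applied.
#'
#' @param table A `series_table`.
#' @return A list of provenance entries (possibly empty).
#' @export
provenance <- function(table) {
  attr(table, "provenance") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
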