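# Filtering and aggregation operators: physical-range QC from the sensor
# specification sheet, midday time-of-day windows, the clear-sky PAR
# filter used before vegetation-index derivation, coverage-aware
# aggregation and gap reporting.

#' Sensor specification
#'
#' Physical measurement range (and accuracy, informational) for one
#' channel, used by [range_check()].
#'
#' @param channel Channel name from [channel_vocabulary()].
#' @param min,max Physical range bounds in channel units (`min < max`).
#' @param accuracy Free-form accuracy description (e.g. `"5% or 5 umol"`).
#' @return A one-row tibble.
#' @export
sensor_spec <- function(channel, min, max, accuracy = NA_character_) {
  if (!channel %in% CHANNELS)
    abort(sprintf("Unknown channel '%s'.", channel))
  if (min >= max) abort("`min` must be less than `max`.")
  tibble(channel = channel, min = as.numeric(min), max = as.numeric(max),
         accuracy = as.character(accuracy))
}

#' Default sensor specifications
#'
#' Physical ranges for every channel in the vocabulary, taken from the
#' manufacturer specification sheets of the sensors commonly deployed
#' (quantum PAR sensors 0-2,500 umol m^-2 s^-1; silicon pyranometers
#' 0-1,280 W m^-2; capacitive RH 0-100 %; tipping-bucket rain gauge up
#' to 1,270 mm/h; soil moisture 0-100 %VWC; air temperature -40 to
#' 123.8 degC, the widest of the deployed thermistor ranges).
#'
#' @return A tibble of [sensor_spec()] rows, one per channel.
#' @export
default_sensor_specs <- function() {
  dplyr::bind_rows(
    sensor_spec("par_in", 0, 2500, "5% or 5 umol"),
    sensor_spec("par_out", 0, 2500, "5% or 5 umol"),
    sensor_spec("sw_in", 0, 1280, "5% or 10 W/m2"),
    sensor_spec("sw_out", 0, 1280, "5% or 10 W/m2"),
    sensor_spec("air_temp", -40, 123.8, "0.3-1.5 degC"),
    sensor_spec("rel_hum", 0, 100, "1.8-4.0 %RH"),
    sensor_spec("soil_moist", 0, 100, "1.0-3.0 %VWC"),
    sensor_spec("rain", 0, 1270, "1%"))
}

#' Flag out-of-range values
#'
#' Values outside a channel's physical range are flagged `out_of_range`;
#' in-range values are untouched (filters and checks never mutate
#' values, only flags and membership). Channels without a specification
#' are skipped with a warning.
#'
#' @param table A `series_table`.
#' @param specs Tibble of [sensor_spec()] rows.
#' @return The table with updated flags; `attr(, "range_counts")` holds
#'   per-channel flagged counts.
#' @export
range_check <- function(table, specs = default_sensor_specs()) {
  stopifnot(inherits(table, "series_table"))
  if (nrow(table) == 0) return(table)
  missing_spec <- setdiff(unique(table$channel), specs$channel)
  if (length(missing_spec) > 0)
    warn(paste0("No sensor spec for channel(s): ",
                paste(missing_spec, collapse = ", "), "; skipped."))
  tb <- dplyr::left_join(as_tibble(table), specs[c("channel", "min", "max")],
                         by = "channel")
  bad <- !is.na(tb$value) & !is.na(tb$min) &
    (tb$value < tb$min | tb$value > tb$max)
  tb$flag[bad] <- "out_of_range"
  counts <- table(tb$channel[bad])
  out <- restore_series(tb[names(table)], table)
  out <- add_provenance(out, list(action = "range_check",
                                  n_flagged = sum(bad)))
  attr(out, "range_counts") <- counts
  out
}

#' Keep records inside a time-of-day window
#'
#' Retains records whose local clock time falls in the half-open window
#' \[`start`, `end`), e.g. the 10:00-14:00 midday window used before
#' vegetation-index derivation. Half-open so boundary samples are never
#' double-counted between adjacent windows.
#'
#' @param table A `series_table`.
#' @param start,end Clock times `"HH:MM"`; default 10:00-14:00.
#' @return The filtered table.
#' @export
window_filter <- function(table, start = "10:00", end = "14:00") {
  stopifnot(inherits(table, "series_table"))
  to_min <- function(x) {
    p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    p[1] * 60 + p[2]
  }
  s <- to_min(start); e <- to_min(end)
  if (e < s) abort("Window must lie within one day (start <= end).")
  m <- clock_minutes(table$timestamp)
  out <- restore_series(as_tibble(table)[m >= s & m < e, ], table)
  add_provenance(out, list(action = "window_filter", start = start, end = end))
}

#' Drop records from cloudy or dim periods
#'
#' Retains only records simultaneous with an incoming-PAR reading
#' strictly above the clear-sky threshold (default 900 umol m^-2 s^-1,
#' the operational cut for "seemingly cloudy" records). The tower's
#' `par_in` applies to the whole deployment, so partner matching is by
#' timestamp. Records at timestamps with no `par_in` partner are dropped
#' and counted in `attr(, "dropped_no_partner")`.
#'
#' @param table A `series_table` containing a `par_in` channel.
#' @param threshold Strict lower bound on `par_in`, umol m^-2 s^-1.
#' @return The filtered table.
#' @export
cloud_filter <- function(table, threshold = 900) {
  stopifnot(inherits(table, "series_table"))
  par_rec <- as_tibble(table)[table$channel == "par_in", ]
  if (nrow(par_rec) == 0)
    abort("cloud_filter requires a par_in channel in the table.",
          class = "phenosense_no_par")
  clear_ts <- unique(par_rec$timestamp[par_rec$flag == "ok" &
                                         !is.na(par_rec$value) &
                                         par_rec$value > threshold])
  has_partner <- table$timestamp %in% unique(par_rec$timestamp)
  keep <- table$timestamp %in% clear_ts
  out <- restore_series(as_tibble(table)[keep, ], table)
  out <- add_provenance(out, list(action = "cloud_filter",
                                  threshold = threshold))
  attr(out, "dropped_no_partner") <- sum(!has_partner)
  out
}

#' Drop records carrying given quality flags
#'
#' @param table A `series_table`.
#' @param flags Flags to exclude (default: everything but `ok`).
#' @return The filtered table.
#' @export
exclude_flags <- function(table, flags = setdiff(FLAGS, "ok")) {
  stopifnot(inherits(table, "series_table"))
  out <- restore_series(as_tibble(table)[!(table$flag %in% flags), ], table)
  add_provenance(out, list(action = "exclude_flags",
                           flags = paste(flags, collapse = ",")))
}

period_start <- function(ts, period) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  if (period == "hourly") {
    lt$min <- 0L; lt$sec <- 0
  } else if (period == "daily") {
    lt$hour <- 0L; lt$min <- 0L; lt$sec <- 0
  } else {
    lt$mday <- 1L; lt$hour <- 0L; lt$min <- 0L; lt$sec <- 0
  }
  as.POSIXct(lt, tz = "UTC")
}

expected_per_bucket <- function(bucket, period, interval_min) {
  if (period == "hourly") return(rep(60 / interval_min, length(bucket)))
  if (period == "daily") return(rep(1440 / interval_min, length(bucket)))
  # monthly: varies with the calendar
  lt <- as.POSIXlt(bucket, tz = "UTC")
  nd <- vapply(seq_along(bucket), function(i) {
    nxt <- lt[i]; nxt$mon <- nxt$mon + 1L
    as.numeric(difftime(as.POSIXct(nxt, tz = "UTC"), bucket[i], units = "days"))
  }, numeric(1))
  nd * 1440 / interval_min
}

#' Aggregate a series table over time buckets
#'
#' One output row per (node, channel, bucket). A bucket is reported only
#' when at least `min_coverage` of its expected samples (given the
#' sampling interval) are present with flag `ok`; under-covered buckets
#' are emitted as explicit gaps (`NA` value, flag `gap`), never as
#' misleading near-empty statistics. Buckets are labelled by their start
#' in local standard time.
#'
#' @param table A `series_table`; exclude unwanted flags first
#'   (see [exclude_flags()]).
#' @param period `"hourly"`, `"daily"` or `"monthly"`.
#' @param statistic `"mean"`, `"min"`, `"max"` or `"count"`.
#' @param interval_min Sampling interval of the input, minutes.
#' @param min_coverage Minimum fraction of expected samples, in (0, 1\].
#' @return A tibble with `bucket`, `node_id`, `channel`, `value`, `n`,
#'   `coverage`, `flag`.
#' @export
aggregate_series <- function(table, period = c("daily", "hourly", "monthly"),
                             statistic = c("mean", "min", "max", "count"),
                             interval_min = 15, min_coverage = 0.75) {
  stopifnot(inherits(table, "series_table"))
  period <- match.arg(period)
  statistic <- match.arg(statistic)
  if (min_coverage <= 0 || min_coverage > 1)
    abort("`min_coverage` must be in (0, 1].")
  tb <- as_tibble(table)
  tb <- tb[tb$flag == "ok" & !is.na(tb$value), ]
  if (nrow(tb) == 0)
    return(tibble(bucket = as.POSIXct(character(), tz = "UTC"),
                  node_id = character(), channel = character(),
                  value = numeric(), n = integer(), coverage = numeric(),
                  flag = character()))
  tb$bucket <- period_start(tb$timestamp, period)
  stat_fun <- switch(statistic, mean = mean, min = min, max = max,
                     count = length)
  out <- tb %>%
    dplyr::group_by(.data$bucket, .data$node_id, .data$channel) %>%
    dplyr::summarise(value = stat_fun(.data$value), n = dplyr::n(),
                     .groups = "drop")
  out$coverage <- out$n / expected_per_bucket(out$bucket, period, interval_min)
  under <- out$coverage < min_coverage
  out$value[under] <- NA_real_
  out$flag <- ifelse(under, "gap", "ok")
  dplyr::arrange(out, .data$node_id, .data$channel, .data$bucket)
}

#' Report gaps in a series table
#'
#' For each (node, channel), reconstructs the expected regular time grid
#' between the first and last observation and reports every maximal run
#' of missing samples as one gap. Records flagged `gap` (sentinel values)
#' count as missing. A per-node downtime summary is attached as
#' `attr(, "downtime")`.
#'
#' @param table A `series_table`.
#' @param interval_min Expected sampling interval, minutes.
#' @return A tibble with `node_id`, `channel`, `gap_start`, `gap_end`
#'   (timestamps of the first and last missing sample) and `n_missing`.
#' @export
gap_report <- function(table, interval_min = 15) {
  stopifnot(inherits(table, "series_table"))
  empty <- tibble(node_id = character(), channel = character(),
                  gap_start = as.POSIXct(character(), tz = "UTC"),
                  gap_end = as.POSIXct(character(), tz = "UTC"),
                  n_missing = integer())
  if (nrow(table) == 0) {
    attr(empty, "downtime") <- tibble(node_id = character(),
                                      downtime_min = numeric())
    return(empty)
  }
  tb <- as_tibble(table)
  present <- tb[tb$flag != "gap" & !is.na(tb$value), ]
  groups <- split(present, paste(present$node_id, present$channel, sep = "\r"))
  gaps <- lapply(groups, function(g) {
    grid <- seq(min(g$timestamp), max(g$timestamp), by = interval_min * 60)
    miss <- !(grid %in% g$timestamp)
    if (!any(miss)) return(NULL)
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    tibble(node_id = g$node_id[1], channel = g$channel[1],
           gap_start = grid[starts[runs]], gap_end = grid[ends[runs]],
           n_missing = r$lengths[runs])
  })
  out <- dplyr::bind_rows(gaps)
  if (nrow(out) == 0) out <- empty
  downtime <- out %>%
    dplyr::group_by(.data$node_id) %>%
    dplyr::summarise(downtime_min = sum(.data$n_missing) * interval_min,
                     .groups = "drop")
  attr(out, "downtime") <- downtime
  out
}
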