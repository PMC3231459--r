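# Timestamp quality assurance. Field clocks drift and — more damagingly —
# get reconfigured to the wrong time zone or to daylight-saving time.
# Sun time exposes this: comparing several days of observed sunrise (from
# the radiation sensors) against astronomical sunrise recovers whole-hour
# timestamp shifts reliably. The method is deliberately limited to whole
# hours; it cannot (and does not try to) correct sub-hour hardware drift.

#' Detect observed sunrise in one day of radiation data
#'
#' Finds the first timestamp at which smoothed irradiance exceeds the
#' detection threshold and stays above it for `persistence` consecutive
#' samples. The threshold is the larger of an absolute floor and a
#' fraction of that day's maximum, which is robust both to sensor zero
#' offsets and to dim (but not fully overcast) days.
#'
#' @param day_series Tibble with `timestamp` and `value` (incoming
#'   shortwave in W m^-2 or PAR in umol m^-2 s^-1) for a single day; gap
#'   records should carry `NA`.
#' @param abs_floor Absolute threshold floor in channel units, default 5.
#' @param rel_frac Fraction of the day's maximum, default 0.02.
#' @param persistence Consecutive samples required above threshold,
#'   default 2.
#' @return The sunrise timestamp, or `NA` (with a `reason` attribute)
#'   when the day never qualifies (overcast, failed, or all-gap).
#' @export
detect_observed_sunrise <- function(day_series, abs_floor = 5,
                                    rel_frac = 0.02, persistence = 2) {
  v <- day_series$value
  ts <- day_series$timestamp
  usable <- !is.na(v)
  if (!any(usable)) {
    out <- NA
    attr(out, "reason") <- "all records missing"
    return(out)
  }
  # 3-point running mean; NA-tolerant at the edges
  sm <- vapply(seq_along(v), function(i) {
    w <- v[max(1, i - 1):min(length(v), i + 1)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  thr <- max(abs_floor, rel_frac * max(sm, na.rm = TRUE))
  above <- !is.na(sm) & sm > thr
  if (!any(above)) {
    out <- NA
    attr(out, "reason") <- "irradiance never exceeds detection threshold"
    return(out)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= persistence)
  if (length(cand) == 0) {
    out <- NA
    attr(out, "reason") <- "no persistent rise above threshold"
    return(out)
  }
  ts[starts[cand[1]]]
}

#' Estimate a whole-hour clock shift from sunrise comparison
#'
#' For each day in the table, detects the observed sunrise in the
#' incoming radiation series and compares it with the astronomical
#' sunrise for the site. The shift estimate is the median per-day offset
#' rounded to the nearest whole hour (the method's stated scope: it is
#' accurate enough for timezone/DST misconfigurations, not for hardware
#' drift). The estimate is refused when fewer than `min_days` days have a
#' detectable sunrise, or when the per-day offsets disperse more than
#' `max_dispersion_min` minutes around the whole-hour estimate.
#'
#' @param table A `series_table` containing `sw_in` or `par_in` for one
#'   node.
#' @param site The deployment's [site_location()].
#' @param channel Radiation channel to use; default `"sw_in"`, falling
#'   back to `"par_in"`.
#' @param min_days Minimum usable days, default 3.
#' @param max_dispersion_min Maximum median absolute deviation of the
#'   per-day offsets from the whole-hour estimate, minutes; default 30.
#' @param ... Passed to [detect_observed_sunrise()].
#' @return A `shift_estimate`: `shift_hours` (signed integer),
#'   `per_day` tibble (`date`, `observed`, `expected`, `offset_min`),
#'   `n_days_used`, `dispersion_min`.
#' @export
estimate_clock_shift <- function(table, site, channel = NULL,
                                 min_days = 3, max_dispersion_min = 30, ...) {
  stopifnot(inherits(table, "series_table"),
            inherits(site, "site_location"))
  if (is.null(channel))
    channel <- if ("sw_in" %in% table$channel) "sw_in" else "par_in"
  rad <- as_tibble(table)[table$channel == channel, ]
  if (nrow(rad) == 0)
    abort(sprintf("No '%s' records to estimate a shift from.", channel),
          class = "phenosense_insufficient_data")
  rad$date <- ps_date(rad$timestamp)
  days <- split(rad, rad$date)
  per_day <- dplyr::bind_rows(lapply(days, function(g) {
    obs <- detect_observed_sunrise(g[c("timestamp", "value")], ...)
    tibble(date = g$date[1],
           observed = if (length(obs) == 1 && is.na(obs))
             as.POSIXct(NA, tz = "UTC") else obs)
  }))
  exp_tab <- expected_sunrise(site, per_day$date)
  per_day$expected <- exp_tab$sunrise
  per_day$offset_min <- as.numeric(difftime(per_day$observed,
                                            per_day$expected,
                                            units = "mins"))
  usable <- per_day[!is.na(per_day$offset_min), ]
  if (nrow(usable) < min_days)
    abort(sprintf(
      "Only %d day(s) with detectable sunrise; need at least %d.",
      nrow(usable), min_days),
      class = "phenosense_insufficient_data")
  shift_hours <- as.integer(round(median(usable$offset_min) / 60))
  dispersion <- median(abs(usable$offset_min - 60 * shift_hours))
  if (dispersion > max_dispersion_min)
    abort(sprintf(
      "Per-day sunrise offsets disperse %.1f min around the %+d h estimate (gate %d min); estimate refused.",
      dispersion, shift_hours, max_dispersion_min),
      class = "phenosense_unreliable_estimate")
  structure(list(shift_hours = shift_hours, per_day = per_day,
                 n_days_used = nrow(usable),
                 dispersion_min = dispersion),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> %+d h from %d day(s); dispersion %.1f min\n",
              x$shift_hours, x$n_days_used, x$dispersion_min))
  invisible(x)
}

#' Correct a series table for an estimated clock shift
#'
#' Translates every timestamp by `-shift_hours`, undoing the injected
#' misconfiguration, and records the correction in the table's
#' provenance. Re-estimating on the corrected table yields a shift of
#' zero, and `apply_shift(apply_shift(t, +k), -k)` returns the original
#' timestamps.
#'
#' @param table A `series_table`.
#' @param est A `shift_estimate` from [estimate_clock_shift()], or a
#'   plain integer number of hours.
#' @return The corrected `series_table`.
#' @export
apply_shift <- function(table, est) {
  stopifnot(inherits(table, "series_table"))
  hours <- if (inherits(est, "shift_estimate")) est$shift_hours else {
    if (est != round(est)) abort("Shift must be a whole number of hours.")
    as.integer(est)
  }
  if (hours == 0) return(table)
  tb <- as_tibble(table)
  tb$timestamp <- tb$timestamp - hours * 3600
  out <- restore_series(tb, table)
  add_provenance(out, list(action = "apply_shift", shift_hours = hours))
}
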