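# Solar geometry after the NOAA/Spencer low-precision algorithm:
# Fourier-series declination and equation of time, true solar time from
# longitude and UTC offset, zenith from the spherical-triangle identity.
# Accuracy is a few hundredths of a degree in declination and well under
# 2 minutes in sunrise time, ample for whole-hour clock-shift detection.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Fractional year (radians) from day-of-year and fractional hour.
frac_year <- function(doy, hour) 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)

solar_decl_rad <- function(g) {
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

# Equation of time, minutes.
eq_time_min <- function(g) {
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

#' Solar zenith angle
#'
#' Zenith angle of the sun (degrees from vertical, 0 = overhead,
#' 90 = geometric horizon) at a site and local-standard-time timestamp.
#' A total function: valid for any timestamp, including polar night.
#'
#' @param site A [site_location()].
#' @param timestamp POSIXct (or parseable character) in local standard time.
#' @return Zenith angle(s) in degrees, in \[0, 180\].
#' @export
#' @examples
#' eq <- site_location(0, 0, 0)
#' solar_zenith(eq, "2010-03-20 12:00:00") # near 0 at equinox noon
solar_zenith <- function(site, timestamp) {
  stopifnot(inherits(site, "site_location"))
  if (is.character(timestamp)) timestamp <- ps_time(timestamp)
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- frac_year(doy, hour)
  decl <- solar_decl_rad(g)
  # true solar time in minutes
  offset <- eq_time_min(g) + 4 * site$longitude - 60 * site$utc_offset_hours
  tst <- hour * 60 + offset
  ha <- deg2rad(tst / 4 - 180)
  lat <- deg2rad(site$latitude)
  cz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  rad2deg(acos(pmin(pmax(cz, -1), 1)))
}

#' Expected sunrise and solar noon
#'
#' Computes, for each date, the expected sunrise time (sun crossing the
#' standard refraction-corrected horizon at -0.833 degrees altitude) and
#' solar noon, both in local standard time. Polar day/night dates are
#' flagged rather than erroring.
#'
#' @param site A [site_location()].
#' @param date A `Date` (or parseable character) vector.
#' @return A tibble with columns `date`, `sunrise` (POSIXct, `NA` on polar
#'   days), `solar_noon` (POSIXct) and `condition`
#'   (`"normal"`, `"polar_day"`, `"polar_night"`).
#' @export
#' @examples
#' expected_sunrise(site_location(0, 0, 0), as.Date("2010-03-20"))
expected_sunrise <- function(site, date) {
  stopifnot(inherits(site, "site_location"))
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  g <- frac_year(doy, 12)
  decl <- solar_decl_rad(g)
  eqt <- eq_time_min(g)
  lat <- deg2rad(site$latitude)
  # hour angle at which the sun centre sits 0.833 deg below the horizon
  cos_ha <- cos(deg2rad(90.833)) / (cos(lat) * cos(decl)) - tan(lat) * tan(decl)
  condition <- rep("normal", length(date))
  condition[cos_ha > 1] <- "polar_night"
  condition[cos_ha < -1] <- "polar_day"
  ha <- rad2deg(acos(pmin(pmax(cos_ha, -1), 1)))
  sunrise_min <- 720 - 4 * (site$longitude + ha) - eqt + 60 * site$utc_offset_hours
  noon_min <- 720 - 4 * site$longitude - eqt + 60 * site$utc_offset_hours
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  sunrise <- day0 + sunrise_min * 60
  sunrise[condition != "normal"] <- NA
  tibble(date = date, sunrise = sunrise,
         solar_noon = day0 + noon_min * 60, condition = condition)
}
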