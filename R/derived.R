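# Derived products: sensor footprint geometry, broadband reflectances and
# vegetation indices from the tower radiation quad, LAI from NDVI, and
# vapour pressure deficit.
#
# The NIR band is approximated as (total shortwave - PAR) in energy
# units: paired pyranometer + quantum-sensor installations measure
# ~300-1100 nm and 400-700 nm, so their difference is dominated by the
# near infrared. This is the standard broadband-radiometer NDVI
# methodology for phenology towers.

#' Ground footprint radius of a radiation sensor
#'
#' Downward-facing radiation flux sensors have a view half-angle of about
#' 85 degrees from nadir with uniform 360-degree rotation, so the ground
#' radius that affects the reading is `radius = tan(view_half_angle) * h`
#' — roughly ten times the mounting height above the monitored surface.
#'
#' @param h Height of the sensor above the monitored surface, metres
#'   (>= 0).
#' @param view_half_angle View half-angle from nadir, degrees in (0, 90);
#'   default 85.
#' @return Footprint radius in metres (vectorised over `h`).
#' @export
#' @examples
#' footprint_radius(5) # about 57 m for a sensor 5 m above the canopy
footprint_radius <- function(h, view_half_angle = 85) {
  if (any(h < 0)) abort("`h` must be >= 0.")
  if (any(view_half_angle <= 0) || any(view_half_angle >= 90))
    abort("`view_half_angle` must be in (0, 90) degrees.")
  tan(deg2rad(view_half_angle)) * h
}

#' Broadband reflectances from a radiation quad
#'
#' Computes PAR-band and NIR-band surface reflectances from the four
#' tower channels. PAR channels are photon fluxes and are converted to
#' energy units with the package quantum factor before the NIR
#' subtraction. Reflectances are only computed when incoming radiation is
#' above a floor (ratios explode near dawn and dusk); out-of-bounds
#' results are flagged, not silently clipped.
#'
#' @param par_in,par_out Incoming/reflected PAR, umol m^-2 s^-1.
#' @param sw_in,sw_out Incoming/reflected total shortwave, W m^-2.
#' @param par_floor Minimum `par_in` (umol m^-2 s^-1) for a defined
#'   result; default 100.
#' @param sw_floor Minimum `sw_in` (W m^-2); default 50.
#' @return A tibble with `rho_par`, `rho_nir` (NA when undefined) and
#'   `status`: `"ok"`, `"low_sun"`, `"no_nir"` (non-positive NIR
#'   denominator) or `"out_of_bounds"` (a reflectance outside \[0, 1\]).
#' @export
broadband_reflectances <- function(par_in, par_out, sw_in, sw_out,
                                   par_floor = 100, sw_floor = 50) {
  n <- max(length(par_in), length(par_out), length(sw_in), length(sw_out))
  par_in <- rep_len(par_in, n); par_out <- rep_len(par_out, n)
  sw_in <- rep_len(sw_in, n); sw_out <- rep_len(sw_out, n)
  rho_par <- rho_nir <- rep(NA_real_, n)
  status <- rep("ok", n)
  low <- is.na(par_in) | is.na(sw_in) | par_in <= par_floor | sw_in <= sw_floor
  status[low] <- "low_sun"
  par_in_w <- par_umol_to_wm2(par_in)
  par_out_w <- par_umol_to_wm2(par_out)
  nir_den <- sw_in - par_in_w
  no_nir <- !low & nir_den <= 0
  status[no_nir] <- "no_nir"
  ok <- !low & !no_nir & !is.na(par_out) & !is.na(sw_out)
  rho_par[ok] <- par_out[ok] / par_in[ok]
  rho_nir[ok] <- (sw_out[ok] - par_out_w[ok]) / nir_den[ok]
  oob <- ok & (rho_par < 0 | rho_par > 1 | rho_nir < 0 | rho_nir > 1)
  status[which(oob)] <- "out_of_bounds"
  tibble(rho_par = rho_par, rho_nir = rho_nir, status = status)
}

#' Normalized Difference Vegetation Index
#'
#' `ndvi = (rho_nir - rho_par) / (rho_nir + rho_par)`; undefined (NA)
#' when the sum is zero. Bounded in \[-1, 1\] whenever both reflectances
#' are in \[0, 1\].
#'
#' @param rho_nir,rho_par Band reflectances, dimensionless.
#' @return NDVI, dimensionless (vectorised).
#' @export
#' @examples
#' ndvi(0.36, 0.03) # 0.33/0.39
ndvi <- function(rho_nir, rho_par) {
  s <- rho_nir + rho_par
  ifelse(is.na(s) | s == 0, NA_real_, (rho_nir - rho_par) / s)
}

#' Two-band Enhanced Vegetation Index (EVI2)
#'
#' The sensor suite has no blue band, so the two-band EVI variant is
#' used: `2.5 * (rho_nir - rho_par) / (rho_nir + 2.4 * rho_par + 1)`.
#'
#' @inheritParams ndvi
#' @return EVI2, dimensionless (vectorised).
#' @export
evi2 <- function(rho_nir, rho_par) {
  2.5 * (rho_nir - rho_par) / (rho_nir + 2.4 * rho_par + 1)
}

#' LAI conversion parameters
#'
#' Ecosystem-specific conversion from NDVI to Leaf Area Index. Two modes:
#' a linear factor (`LAI = c * NDVI`) or a saturating Beer-law style form
#' `LAI = -(1/k) * ln((ndvi_max - ndvi) / (ndvi_max - ndvi_min))`. The
#' conversion is characteristic of each ecosystem and must be supplied by
#' the user — there are no built-in ecosystem values.
#'
#' @param mode `"linear"` or `"saturating"`.
#' @param c Linear factor (> 0), linear mode.
#' @param ndvi_min,ndvi_max NDVI at bare ground / at saturation
#'   (`ndvi_min < ndvi_max`), saturating mode.
#' @param k Extinction coefficient (> 0), saturating mode.
#' @return A `lai_params` object.
#' @export
lai_params <- function(mode = c("linear", "saturating"), c = NULL,
                       ndvi_min = NULL, ndvi_max = NULL, k = NULL) {
  mode <- match.arg(mode)
  if (mode == "linear") {
    if (is.null(c) || c <= 0) abort("Linear mode needs `c` > 0.")
  } else {
    if (is.null(ndvi_min) || is.null(ndvi_max) || is.null(k))
      abort("Saturating mode needs `ndvi_min`, `ndvi_max` and `k`.")
    if (ndvi_min >= ndvi_max) abort("`ndvi_min` must be below `ndvi_max`.")
    if (k <= 0) abort("`k` must be > 0.")
  }
  structure(list(mode = mode, c = c, ndvi_min = ndvi_min,
                 ndvi_max = ndvi_max, k = k), class = "lai_params")
}

#' Leaf Area Index from NDVI
#'
#' Applies an ecosystem-specific [lai_params()] conversion. In linear
#' mode negative NDVI maps to zero LAI. In saturating mode NDVI at or
#' above `ndvi_max` is clipped just below saturation and flagged in the
#' `clipped` attribute.
#'
#' @param x NDVI values.
#' @param params A [lai_params()].
#' @return LAI in m^2 m^-2 (vectorised); saturating mode attaches a
#'   logical `clipped` attribute.
#' @export
lai_from_ndvi <- function(x, params) {
  stopifnot(inherits(params, "lai_params"))
  if (params$mode == "linear") return(params$c * pmax(x, 0))
  eps <- 1e-6
  clipped <- !is.na(x) & x >= params$ndvi_max
  xc <- pmin(x, params$ndvi_max - eps)
  out <- -(1 / params$k) *
    log((params$ndvi_max - xc) / (params$ndvi_max - params$ndvi_min))
  attr(out, "clipped") <- clipped
  out
}

#' Vapour Pressure Deficit
#'
#' Saturation vapour pressure by the Magnus formula,
#' `es = 0.6108 * exp(17.27 * T / (T + 237.3))` (kPa), and
#' `vpd = es * (1 - RH / 100)`.
#'
#' @param temp_c Air temperature, degrees Celsius.
#' @param rel_hum Relative humidity, percent in \[0, 100\] (QC should
#'   already have removed anything outside; values outside error).
#' @return VPD in kPa (vectorised).
#' @export
#' @examples
#' vpd(25, 50) # about 1.58 kPa
vpd <- function(temp_c, rel_hum) {
  if (any(!is.na(rel_hum) & (rel_hum < 0 | rel_hum > 100)))
    abort("`rel_hum` outside [0, 100]; run range_check first.")
  es <- 0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
  es * (1 - rel_hum / 100)
}

#' Daily NDVI from a tower series
#'
#' The standard derivation chain for a phenology tower: restrict to the
#' midday window, drop cloudy records (incoming PAR at or below the
#' threshold), compute instantaneous reflectances and NDVI per timestamp
#' from the radiation quad, then average per day. Indices are computed on
#' instantaneous records and then aggregated (mean of ratios, not ratio
#' of means).
#'
#' @param table A `series_table` containing the four tower radiation
#'   channels for `node`.
#' @param node Node carrying the radiation quad, default `"tower"`.
#' @param window_start,window_end Midday window, default 10:00-14:00.
#' @param par_threshold Clear-sky PAR threshold, umol m^-2 s^-1
#'   (strict >), default 900.
#' @param min_records Minimum clear instantaneous NDVI records for a
#'   daily value; days with fewer are omitted.
#' @return A tibble with `date`, `ndvi`, `evi2`, `n` (records averaged).
#' @export
derive_daily_ndvi <- function(table, node = "tower",
                              window_start = "10:00", window_end = "14:00",
                              par_threshold = 900, min_records = 3) {
  stopifnot(inherits(table, "series_table"))
  tb <- restore_series(as_tibble(table)[table$node_id == node &
    table$channel %in% c("par_in", "par_out", "sw_in", "sw_out"), ], table)
  tb <- exclude_flags(tb)
  tb <- window_filter(tb, window_start, window_end)
  tb <- cloud_filter(tb, threshold = par_threshold)
  wide <- tidyr::pivot_wider(as_tibble(tb)[c("timestamp", "channel", "value")],
                             names_from = "channel", values_from = "value")
  need <- c("par_in", "par_out", "sw_in", "sw_out")
  if (!all(need %in% names(wide)) || nrow(wide) == 0)
    return(tibble(date = as.Date(character()), ndvi = numeric(),
                  evi2 = numeric(), n = integer()))
  wide <- wide[stats::complete.cases(wide[need]), ]
  refl <- broadband_reflectances(wide$par_in, wide$par_out,
                                 wide$sw_in, wide$sw_out)
  keep <- refl$status == "ok"
  inst <- tibble(date = ps_date(wide$timestamp[keep]),
                 ndvi = ndvi(refl$rho_nir[keep], refl$rho_par[keep]),
                 evi2 = evi2(refl$rho_nir[keep], refl$rho_par[keep]))
  inst %>%
    dplyr::group_by(.data$date) %>%
    dplyr::summarise(ndvi = mean(.data$ndvi), evi2 = mean(.data$evi2),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$n >= min_records)
}
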