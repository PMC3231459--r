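# Synthetic deployment generator. Emulates the data a phenology tower and
# an understory node network would produce — diurnal clear-sky irradiance,
# canopy reflectance following a prescribed seasonal NDVI trajectory,
# air temperature / relative humidity cycles — plus the defects field
# deployments actually suffer: whole-hour clock shifts, sensor failure
# windows, and structurally corrupted logger records. Everything is
# seeded, so downstream QA can be tested against exact ground truth.

#' Synthetic generation configuration
#'
#' @param start_date First simulated day (`Date` or parseable character).
#' @param n_days Number of simulated days.
#' @param sampling_interval Minutes between records (must divide 1440);
#'   15 min is the typical logger configuration.
#' @param clear_sky_peak_shortwave Clear-sky shortwave irradiance at zero
#'   zenith angle, W m^-2.
#' @param par_fraction Fraction of shortwave energy in the PAR band
#'   (400-700 nm), dimensionless in (0, 1).
#' @param canopy_ndvi_trajectory Function of day-of-year returning the
#'   target canopy NDVI; the default is a logistic green-up from 0.25 to
#'   0.75 centred on day 120, typical of a seasonally dry forest.
#' @param cloudy_day_probability Probability that a simulated day is
#'   overcast (irradiance scaled well below the clear-sky curve).
#' @param noise_sd Named list of noise levels: `radiation_rel`
#'   (multiplicative SD, fraction of signal, for the four radiation
#'   channels), `air_temp` (additive SD, degC), `rel_hum` (additive SD,
#'   %RH). Defaults follow typical sensor accuracies (5 %, 0.3 degC,
#'   2.5 %RH).
#' @param random_seed Required integer seed; there is no hidden global
#'   RNG state.
#' @return A `synth_config` object.
#' @export
synth_config <- function(start_date = "2010-01-01", n_days = 7,
                         sampling_interval = 15,
                         clear_sky_peak_shortwave = 1000,
                         par_fraction = 0.45,
                         canopy_ndvi_trajectory = function(doy)
                           0.25 + 0.5 / (1 + exp(-(doy - 120) / 15)),
                         cloudy_day_probability = 0.2,
                         noise_sd = list(radiation_rel = 0.05,
                                         air_temp = 0.3, rel_hum = 2.5),
                         random_seed) {
  if (missing(random_seed)) abort("`random_seed` is required.")
  if (1440 %% sampling_interval != 0)
    abort("`sampling_interval` must divide 1440 minutes.")
  if (par_fraction <= 0 || par_fraction >= 1)
    abort("`par_fraction` must be in (0, 1).")
  if (cloudy_day_probability < 0 || cloudy_day_probability > 1)
    abort("`cloudy_day_probability` must be in [0, 1].")
  if (any(unlist(noise_sd) < 0)) abort("Noise SDs must be >= 0.")
  stopifnot(is.function(canopy_ndvi_trajectory))
  structure(list(start_date = as.Date(start_date), n_days = as.integer(n_days),
                 sampling_interval = as.integer(sampling_interval),
                 clear_sky_peak_shortwave = clear_sky_peak_shortwave,
                 par_fraction = par_fraction,
                 canopy_ndvi_trajectory = canopy_ndvi_trajectory,
                 cloudy_day_probability = cloudy_day_probability,
                 noise_sd = noise_sd,
                 random_seed = as.integer(random_seed)),
            class = "synth_config")
}

#' Defect specification for synthetic deployments
#'
#' Describes the faults to inject: a whole-hour timestamp shift (the kind
#' a misconfigured field laptop causes), per-sensor failure windows, and
#' the rate of structural record corruption applied when logger files are
#' written.
#'
#' @param clock_shift_hours Signed whole hours added to every emitted
#'   timestamp.
#' @param failure_windows Tibble with columns `node_id`, `channel`,
#'   `start`, `end` (POSIXct or parseable character, local standard time):
#'   records inside a window are not emitted, as from a dead sensor.
#' @param corruption_rate Fraction of written logger records to corrupt,
#'   in \[0, 1\] (consumed by [write_logger_file()]).
#' @return A `defect_spec` object.
#' @export
defect_spec <- function(clock_shift_hours = 0, failure_windows = NULL,
                        corruption_rate = 0) {
  if (clock_shift_hours != round(clock_shift_hours))
    abort("`clock_shift_hours` must be a whole number of hours.")
  if (corruption_rate < 0 || corruption_rate > 1)
    abort("`corruption_rate` must be in [0, 1].")
  if (!is.null(failure_windows)) {
    failure_windows <- as_tibble(failure_windows)
    stopifnot(all(c("node_id", "channel", "start", "end") %in%
                    names(failure_windows)))
    if (is.character(failure_windows$start))
      failure_windows$start <- ps_time(failure_windows$start)
    if (is.character(failure_windows$end))
      failure_windows$end <- ps_time(failure_windows$end)
    if (any(failure_windows$end <= failure_windows$start))
      abort("Inconsistent defect windows: `end` must be after `start`.")
  }
  structure(list(clock_shift_hours = as.integer(clock_shift_hours),
                 failure_windows = failure_windows,
                 corruption_rate = corruption_rate),
            class = "defect_spec")
}

#' Clear-sky irradiance for one day
#'
#' Generates per-timestamp incoming shortwave and PAR for a clear day:
#' irradiance is zero whenever the sun is at or below the geometric
#' horizon and rises smoothly, proportional to the cosine of the solar
#' zenith angle, to a midday maximum bounded by
#' `clear_sky_peak_shortwave`. PAR is `par_fraction` of the shortwave
#' energy, reported as photon flux via the package-wide quantum
#' conversion.
#'
#' @param site A [site_location()].
#' @param date The simulated day.
#' @param cfg A [synth_config()].
#' @return A tibble with `timestamp` (interval start, local standard
#'   time), `sw_in` (W m^-2), `par_in` (umol m^-2 s^-1); the `condition`
#'   attribute flags polar day/night.
#' @export
make_clear_sky_day <- function(site, date, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  date <- as.Date(date)
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  ts <- day0 + seq(0, 1440 - cfg$sampling_interval,
                   by = cfg$sampling_interval) * 60
  z <- solar_zenith(site, ts)
  cz <- pmax(cos(deg2rad(z)), 0)
  sw <- cfg$clear_sky_peak_shortwave * cz
  par <- par_wm2_to_umol(cfg$par_fraction * sw)
  out <- tibble(timestamp = ts, sw_in = sw, par_in = par)
  cond <- expected_sunrise(site, date)$condition
  attr(out, "condition") <- cond
  out
}

# Reflectance in the PAR band assigned to the synthetic canopy; the NIR
# reflectance is then solved from the prescribed NDVI.
SYNTH_RHO_PAR <- 0.05

rho_nir_for_ndvi <- function(ndvi, rho_par = SYNTH_RHO_PAR) {
  rho_par * (1 + ndvi) / (1 - ndvi)
}

#' Generate a full synthetic deployment
#'
#' Produces (a) a phenology-tower radiation quad (node `"tower"`:
#' `par_in`, `par_out`, `sw_in`, `sw_out`) whose reflectance ratios
#' reproduce the configured NDVI trajectory exactly before noise, (b)
#' understory air temperature and relative humidity with diurnal cycles
#' for every node in the geometry, and (c) a ground-truth record of the
#' prescribed daily NDVI, the injected clock shift, failure windows and
#' overcast days. Identical configuration, defects and seed give
#' byte-identical output.
#'
#' @param geom A [deployment_geometry()] with at least one node.
#' @param cfg A [synth_config()].
#' @param defects A [defect_spec()].
#' @return A list with `table` (a [series_table()]) and `truth` (list:
#'   `daily_ndvi` tibble, `clock_shift_hours`, `failure_windows`,
#'   `cloudy_days`, `seed`).
#' @export
make_deployment_series <- function(geom, cfg, defects = defect_spec()) {
  stopifnot(inherits(geom, "deployment_geometry"),
            inherits(cfg, "synth_config"),
            inherits(defects, "defect_spec"))
  if (nrow(geom$nodes) < 1) abort("Geometry must contain at least one node.")
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  span <- c(as.POSIXct(paste(format(dates[1]), "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(format(dates[cfg$n_days]), "23:59:59"), tz = "UTC"))
  if (!is.null(defects$failure_windows)) {
    fw <- defects$failure_windows
    if (any(fw$start < span[1]) || any(fw$end > span[2] + 1))
      abort("Inconsistent defect windows: outside the simulated span.")
    known_nodes <- c("tower", geom$nodes$node_id)
    if (!all(fw$node_id %in% known_nodes))
      abort("Inconsistent defect windows: unknown node id(s).")
  }

  gen <- function() {
    doy <- as.integer(strftime(dates, "%j", tz = "UTC"))
    ndvi_day <- cfg$canopy_ndvi_trajectory(doy)
    if (any(ndvi_day <= -1 | ndvi_day > 0.9))
      abort("NDVI trajectory must stay in (-1, 0.9] so reflectances stay in [0, 1].")
    cloudy <- stats::runif(cfg$n_days) < cfg$cloudy_day_probability
    cloud_factor <- ifelse(cloudy, stats::runif(cfg$n_days, 0.05, 0.25), 1)

    nrel <- cfg$noise_sd$radiation_rel %||% 0
    tsd <- cfg$noise_sd$air_temp %||% 0
    hsd <- cfg$noise_sd$rel_hum %||% 0
    node_t_offset <- stats::rnorm(nrow(geom$nodes), 0, 0.5)
    node_h_offset <- stats::rnorm(nrow(geom$nodes), 0, 2)

    day_tabs <- lapply(seq_along(dates), function(i) {
      sky <- make_clear_sky_day(geom$site, dates[i], cfg)
      sw_in <- sky$sw_in * cloud_factor[i]
      par_in <- sky$par_in * cloud_factor[i]
      rho_p <- SYNTH_RHO_PAR
      rho_n <- rho_nir_for_ndvi(ndvi_day[i])
      par_out <- rho_p * par_in
      par_in_w <- par_umol_to_wm2(par_in)
      par_out_w <- par_umol_to_wm2(par_out)
      sw_out <- par_out_w + rho_n * (sw_in - par_in_w)

      noisy <- function(v) if (nrel > 0)
        pmax(v * (1 + stats::rnorm(length(v), 0, nrel)), 0) else v
      tower <- dplyr::bind_rows(
        tibble(timestamp = sky$timestamp, node_id = "tower",
               channel = "par_in", value = noisy(par_in)),
        tibble(timestamp = sky$timestamp, node_id = "tower",
               channel = "par_out", value = noisy(par_out)),
        tibble(timestamp = sky$timestamp, node_id = "tower",
               channel = "sw_in", value = noisy(sw_in)),
        tibble(timestamp = sky$timestamp, node_id = "tower",
               channel = "sw_out", value = noisy(sw_out)))

      hod <- clock_minutes(sky$timestamp) / 60
      t_base <- 25 + 6 * cos(2 * pi * (hod - 15) / 24)
      under <- dplyr::bind_rows(lapply(seq_len(nrow(geom$nodes)), function(k) {
        tk <- t_base + node_t_offset[k] +
          if (tsd > 0) stats::rnorm(length(hod), 0, tsd) else 0
        rh <- 70 - 4 * (t_base - 25) + node_h_offset[k] +
          if (hsd > 0) stats::rnorm(length(hod), 0, hsd) else 0
        dplyr::bind_rows(
          tibble(timestamp = sky$timestamp, node_id = geom$nodes$node_id[k],
                 channel = "air_temp", value = tk),
          tibble(timestamp = sky$timestamp, node_id = geom$nodes$node_id[k],
                 channel = "rel_hum", value = pmin(pmax(rh, 2), 100)))
      }))
      dplyr::bind_rows(tower, under)
    })

    tb <- dplyr::bind_rows(day_tabs)
    tb$flag <- "ok"

    if (!is.null(defects$failure_windows)) {
      for (j in seq_len(nrow(defects$failure_windows))) {
        w <- defects$failure_windows[j, ]
        drop <- tb$node_id == w$node_id & tb$channel == w$channel &
          tb$timestamp >= w$start & tb$timestamp <= w$end
        tb <- tb[!drop, ]
      }
    }
    if (defects$clock_shift_hours != 0)
      tb$timestamp <- tb$timestamp + defects$clock_shift_hours * 3600

    tb <- dplyr::arrange(tb, .data$node_id, .data$channel, .data$timestamp)
    list(table = new_series_table(tb, provenance = list(list(
           action = "synthesize", seed = cfg$random_seed,
           n_days = cfg$n_days, clock_shift_hours = defects$clock_shift_hours))),
         truth = list(
           daily_ndvi = tibble(date = dates, ndvi = ndvi_day),
           clock_shift_hours = defects$clock_shift_hours,
           failure_windows = defects$failure_windows,
           cloudy_days = dates[cloudy],
           seed = cfg$random_seed))
  }
  withr::with_seed(cfg$random_seed, gen())
}

#' Write a ground-truth sidecar file
#'
#' Serialises the `truth` record of [make_deployment_series()] as a YAML
#' sidecar next to the logger files, so that QA test harnesses can find
#' the injected defects without touching the data path.
#'
#' @param truth The `truth` element of [make_deployment_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    daily_ndvi = lapply(seq_len(nrow(truth$daily_ndvi)), function(i)
      list(date = format(truth$daily_ndvi$date[i]),
           ndvi = truth$daily_ndvi$ndvi[i])),
    clock_shift_hours = truth$clock_shift_hours,
    cloudy_days = as.character(format(truth$cloudy_days)),
    seed = truth$seed)
  if (!is.null(truth$failure_windows))
    out$failure_windows <- lapply(seq_len(nrow(truth$failure_windows)),
      function(i) list(
        node_id = truth$failure_windows$node_id[i],
        channel = truth$failure_windows$channel[i],
        start = format(truth$failure_windows$start[i]),
        end = format(truth$failure_windows$end[i])))
  yaml::write_yaml(out, path)
  invisible(path)
}
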