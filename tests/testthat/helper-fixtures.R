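# Shared fixtures: a reference equatorial site (longitude 0, UTC+0 keeps
# clock time close to solar time) and small seeded deployments.

eq_site <- function() site_location(0, 0, 0)

quiet_cfg <- function(seed, n_days = 7, ...) {
  synth_config(random_seed = seed, n_days = n_days,
               cloudy_day_probability = 0,
               noise_sd = list(radiation_rel = 0, air_temp = 0, rel_hum = 0),
               ...)
}

small_geom <- function(site = eq_site()) {
  deployment_geometry(site,
    tibble::tibble(node_id = c("n1", "n2"), x = c(0, 20), y = c(0, 0),
                   height = 1.5))
}

# Compare the records of two series tables, ignoring provenance and
# other bookkeeping attributes.
expect_same_records <- function(a, b) {
  bare <- function(x) {
    x <- as.data.frame(x)[c("timestamp", "node_id", "channel",
                            "value", "flag")]
    attributes(x) <- attributes(x)[c("names", "row.names", "class")]
    rownames(x) <- NULL
    x
  }
  testthat::expect_equal(bare(a), bare(b))
}

# Day-internal scatter of the instantaneous NDVI records that enter the
# daily mean: an independent route to the daily estimator's standard error.
daily_ndvi_se <- function(table) {
  tb <- cloud_filter(window_filter(exclude_flags(table)))
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(tb)[tb$node_id == "tower",
                          c("timestamp", "channel", "value")],
    names_from = "channel", values_from = "value")
  r <- broadband_reflectances(wide$par_in, wide$par_out,
                              wide$sw_in, wide$sw_out)
  inst <- tibble::tibble(date = ps_date(wide$timestamp),
                         ndvi = ndvi(r$rho_nir, r$rho_par))[r$status == "ok", ]
  dplyr::summarise(dplyr::group_by(inst, date),
                   se = stats::sd(ndvi) / sqrt(dplyr::n()), .groups = "drop")
}

# A regular one-channel table of n records for ingestion fixtures.
regular_table <- function(n, channel = "air_temp", node = "n1",
                          start = "2010-01-01 00:00:00", interval_min = 15) {
  ts <- ps <- as.POSIXct(start, tz = "UTC") +
    (seq_len(n) - 1) * interval_min * 60
  series_table(timestamp = ts, node_id = rep(node, n),
               channel = rep(channel, n),
               value = 20 + sin(seq_len(n) / 10), flag = rep("ok", n))
}
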