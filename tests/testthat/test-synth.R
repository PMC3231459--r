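# The synthetic generator is the ground-truth source for every QA test:
# its irradiance must respect day/night geometry, its NDVI construction
# must be exactly invertible, and it must be bit-reproducible under a seed.

test_that("clear-sky irradiance is zero at night and non-negative everywhere", {
  cfg <- quiet_cfg(1)
  day <- make_clear_sky_day(eq_site(), "2010-03-20", cfg)
  z <- solar_zenith(eq_site(), day$timestamp)
  expect_true(all(day$sw_in[z >= 90] == 0))
  expect_true(all(day$sw_in >= 0))
  expect_true(all(day$par_in >= 0))
  # midnight sample is dark
  expect_equal(day$sw_in[1], 0)
  # PAR is the configured energy fraction via the quantum conversion
  expect_equal(day$par_in, par_wm2_to_umol(cfg$par_fraction * day$sw_in))
  # midday maximum bounded by the configured clear-sky peak
  expect_lte(max(day$sw_in), cfg$clear_sky_peak_shortwave)
})

test_that("clear days have midday PAR above the cloud-filter threshold", {
  cfg <- quiet_cfg(3, n_days = 7)
  out <- make_deployment_series(small_geom(), cfg)
  midday <- window_filter(out$table)
  par_mid <- midday[midday$channel == "par_in", ]
  daily_max <- tapply(par_mid$value, ps_date(par_mid$timestamp), max)
  expect_length(daily_max, 7)
  expect_true(all(daily_max > 900))
})

test_that("prescribed NDVI is recovered to machine precision without noise", {
  cfg <- quiet_cfg(11, canopy_ndvi_trajectory = function(doy)
    0.3 + 0.4 * (doy %% 7) / 7)
  out <- make_deployment_series(small_geom(), cfg)
  got <- derive_daily_ndvi(out$table)
  expect_equal(got$ndvi, out$truth$daily_ndvi$ndvi, tolerance = 1e-12)
})

test_that("an injected clock shift moves every emitted timestamp by that amount", {
  g <- small_geom()
  base <- make_deployment_series(g, quiet_cfg(5))
  shifted <- make_deployment_series(g, quiet_cfg(5),
                                    defect_spec(clock_shift_hours = 1))
  expect_equal(as.numeric(difftime(shifted$table$timestamp,
                                   base$table$timestamp, units = "secs")),
               rep(3600, nrow(base$table)))
  expect_identical(shifted$truth$clock_shift_hours, 1L)
})

test_that("identical config + defects + seed give identical output", {
  g <- small_geom()
  cfg <- synth_config(random_seed = 99, n_days = 3)  # defaults: clouds + noise on
  a <- make_deployment_series(g, cfg)
  b <- make_deployment_series(g, cfg)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth$daily_ndvi, b$truth$daily_ndvi)
  expect_identical(a$truth$cloudy_days, b$truth$cloudy_days)
})

test_that("failure windows are validated against the simulated span", {
  g <- small_geom()
  bad <- defect_spec(failure_windows = tibble::tibble(
    node_id = "n1", channel = "air_temp",
    start = ps_time("2011-06-01 00:00:00"), end = ps_time("2011-06-02 00:00:00")))
  expect_error(make_deployment_series(g, quiet_cfg(1), bad),
               "outside the simulated span")
  bad_node <- defect_spec(failure_windows = tibble::tibble(
    node_id = "ghost", channel = "air_temp",
    start = ps_time("2010-01-02 00:00:00"), end = ps_time("2010-01-03 00:00:00")))
  expect_error(make_deployment_series(g, quiet_cfg(1), bad_node),
               "unknown node")
  expect_error(defect_spec(failure_windows = tibble::tibble(
    node_id = "n1", channel = "air_temp",
    start = ps_time("2010-01-02 00:00:00"),
    end = ps_time("2010-01-01 00:00:00"))), "end.*after.*start")
})

test_that("logger files round-trip through both built-in dialects", {
  g <- small_geom()
  out <- make_deployment_series(g, quiet_cfg(21, n_days = 2))
  tower <- restore_series(
    as_tibble(out$table)[out$table$node_id == "tower", ], out$table)
  under <- restore_series(
    as_tibble(out$table)[out$table$node_id != "tower", ], out$table)

  f1 <- withr::local_tempfile(fileext = ".csv")
  write_logger_file(tower, "tower_wide", f1)
  back <- parse_logger_file(f1, "tower_wide")
  expect_equal(nrow(back$table), nrow(tower))
  expect_equal(back$table$value, tower$value, tolerance = 1e-9)
  expect_equal(back$table$timestamp, tower$timestamp)
  expect_identical(back$report$counts[["malformed"]], 0L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_logger_file(under, "wireless_long", f2)
  back2 <- parse_logger_file(f2, "wireless_long")
  expect_equal(nrow(back2$table), nrow(under))
  expect_equal(back2$table$value, under$value, tolerance = 1e-9)
})

test_that("an empty table writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_logger_file(series_table(), "wireless_long", f)
  expect_length(readLines(f), 1)
})

test_that("wide data records carry one timestamp plus one column per channel", {
  tb <- make_deployment_series(small_geom(), quiet_cfg(2, n_days = 1))$table
  tower <- restore_series(as_tibble(tb)[tb$node_id == "tower" &
    tb$channel %in% c("par_in", "sw_in", "sw_out"), ], tb)
  f <- withr::local_tempfile(fileext = ".csv")
  write_logger_file(tower, "tower_wide", f)
  lines <- readLines(f)
  fields <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
  expect_true(all(lengths(fields) == 4))  # timestamp + 3 channels
})

test_that("unknown dialects are rejected with the registered list", {
  expect_error(write_logger_file(series_table(), "nonsense", tempfile()),
               "Registered dialects", class = "phenosense_unknown_dialect")
})

test_that("corruption fraction respects the binomial 99% interval", {
  tb <- regular_table(1000)
  f <- withr::local_tempfile(fileext = ".tsv")
  res <- write_logger_file(tb, "wireless_long", f,
                           corruption_rate = 0.1, seed = 404)
  k <- nrow(res$corrupted)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  # and the draw is reproducible under the same seed
  res2 <- write_logger_file(tb, "wireless_long",
                            withr::local_tempfile(fileext = ".tsv"),
                            corruption_rate = 0.1, seed = 404)
  expect_identical(res$corrupted, res2$corrupted)
})

test_that("ground truth sidecar round-trips through YAML", {
  out <- make_deployment_series(small_geom(), quiet_cfg(31, n_days = 2),
    defect_spec(clock_shift_hours = 2, failure_windows = tibble::tibble(
      node_id = "n1", channel = "air_temp",
      start = ps_time("2010-01-01 06:00:00"),
      end = ps_time("2010-01-01 12:00:00"))))
  f <- withr::local_tempfile(fileext = ".yml")
  write_ground_truth(out$truth, f)
  got <- yaml::read_yaml(f)
  expect_equal(got$clock_shift_hours, 2)
  expect_equal(got$seed, 31)
  expect_length(got$daily_ndvi, 2)
  expect_equal(got$failure_windows[[1]]$node_id, "n1")
})
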