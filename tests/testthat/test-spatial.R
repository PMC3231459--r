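# Spatial layer: deterministic layout geometry, IDW exactness and
# boundedness, the working/installed reliability definition, and the
# frame cadence of animated field sequences.

test_that("layouts place nodes where the strategy says", {
  g <- layout_grid(eq_site(), 3, 4, 10)
  expect_identical(nrow(g$nodes), 12L)
  expect_setequal(unique(g$nodes$x), c(0, 10, 20, 30))
  expect_identical(g$layout_kind, "grid")

  tr <- layout_transect(eq_site(), 100, 5)
  expect_identical(nrow(tr$nodes), 5L)
  expect_equal(diff(tr$nodes$x), rep(25, 4))
  expect_true(all(tr$nodes$y == 0))  # collinear

  st <- layout_star(eq_site(), ring_radii = c(10, 20), ring_counts = c(2, 4))
  d <- sqrt(st$nodes$x^2 + st$nodes$y^2)
  expect_equal(d, c(10, 10, 20, 20, 20, 20))

  expect_error(layout_transect(eq_site(), 100, 0), ">= 1")
  expect_error(deployment_geometry(eq_site(),
    tibble::tibble(node_id = c("a", "a"), x = 0:1, y = 0:1)), "unique")
})

test_that("IDW is exact at nodes, constant-preserving, and bounded by extremes", {
  g <- layout_grid(eq_site(), 2, 2, 10)
  ids <- g$nodes$node_id

  const <- idw_interpolate(g, setNames(rep(4.2, 4), ids), cell_size = 2)
  expect_true(all(abs(const$values - 4.2) < 1e-12))

  r <- setNames(c(10, 20, 30, 40), ids)
  ras <- idw_interpolate(g, r, cell_size = 2)
  # exactness at a node's cell (node at x=0, y=0 coincides with no cell
  # centre in general, so interpolate on a grid aligned with the nodes)
  ras2 <- idw_interpolate(g, r, cell_size = 2,
                          extent = c(xmin = -1, xmax = 11, ymin = -1, ymax = 11))
  tib <- as_tibble(ras2)
  at_origin <- tib[abs(tib$x - 0) < 1e-9 & abs(tib$y - 0) < 1e-9, ]
  expect_equal(at_origin$value, r[["g01_01"]])
  # convex combination: never outside the input extremes
  expect_true(all(ras$values >= 10 & ras$values <= 40, na.rm = TRUE))

  # midpoint of two nodes with p = 2: equal weights, arithmetic mean
  g2 <- deployment_geometry(eq_site(),
    tibble::tibble(node_id = c("a", "b"), x = c(0, 10), y = 0))
  mid <- idw_interpolate(g2, c(a = 10, b = 30), cell_size = 1,
                         extent = c(xmin = 4.5, xmax = 5.5,
                                    ymin = -0.5, ymax = 0.5))
  expect_equal(as.vector(mid$values), 20)

  # no contributing nodes: all-undefined raster, not an error
  none <- idw_interpolate(g, setNames(rep(NA_real_, 4), ids), cell_size = 5)
  expect_true(all(is.na(none$values)))
})

test_that("reliability is the working/installed ratio within the coverage radius", {
  g2 <- deployment_geometry(eq_site(),
    tibble::tibble(node_id = c("a", "b"), x = c(0, 10), y = 0))
  ext <- c(xmin = -0.5, xmax = 10.5, ymin = -0.5, ymax = 0.5)

  all_ok <- reliability_map(g2, c(a = TRUE, b = TRUE), cell_size = 1,
                            radius = 8, extent = ext)
  covered <- !is.na(all_ok$values) & all_ok$values > 0
  expect_true(all(all_ok$values[covered] == 1))

  half <- reliability_map(g2, c(a = TRUE, b = FALSE), cell_size = 1,
                          radius = 8, extent = ext)
  tib <- as_tibble(half)
  both_cover <- tib[abs(tib$x - 5) < 1e-9, ]  # midpoint: in range of both
  expect_equal(both_cover$value, 0.5)
  only_a <- tib[abs(tib$x - 1) < 1e-9, ]      # 1 m from a, 9 m from b
  expect_equal(only_a$value, 1)

  far <- reliability_map(g2, c(a = TRUE, b = TRUE), cell_size = 1,
                         radius = 2,
                         extent = c(xmin = 4.5, xmax = 5.5,
                                    ymin = -0.5, ymax = 0.5))
  expect_equal(as.vector(far$values), 0)  # beyond r of every node

  # cell-wise monotone non-increasing in the number of failures
  r0 <- reliability_map(g2, c(a = TRUE, b = TRUE), 1, radius = 8, extent = ext)
  r1 <- reliability_map(g2, c(a = TRUE, b = FALSE), 1, radius = 8, extent = ext)
  r2 <- reliability_map(g2, c(a = FALSE, b = FALSE), 1, radius = 8, extent = ext)
  expect_true(all(r1$values <= r0$values))
  expect_true(all(r2$values <= r1$values))
})

test_that("frame sequences keep cadence through failures and mark them in reliability", {
  g <- small_geom()
  fw <- tibble::tibble(node_id = "n2", channel = "air_temp",
                       start = ps_time("2010-01-01 08:00:00"),
                       end = ps_time("2010-01-01 10:59:59"))
  out <- make_deployment_series(g, quiet_cfg(70, n_days = 1),
                                defect_spec(failure_windows = fw))
  frames <- frame_sequence(g, out$table, "air_temp", period = "hourly",
                           cell_size = 5, radius = 30)
  expect_length(frames, 24)  # one frame per hourly bucket, failures or not
  hours <- vapply(frames, function(f) format(f$bucket, "%H"), "")
  expect_identical(hours, sprintf("%02d", 0:23))
  # during the outage the affected frames lose reliability, others do not
  rel_mean <- vapply(frames, function(f) mean(f$reliability), numeric(1))
  expect_true(all(rel_mean[9:11] < rel_mean[1]))
  expect_true(all(rel_mean[-(9:11)] == rel_mean[1]))
})

test_that("constant input yields identical frames and a raster CSV round-trips", {
  n <- 24 * 4
  ts <- ps_time("2010-01-01 00:00:00") + (seq_len(n) - 1) * 900
  tb <- dplyr::bind_rows(
    tibble::tibble(timestamp = ts, node_id = "n1", channel = "air_temp",
                   value = 20, flag = "ok"),
    tibble::tibble(timestamp = ts, node_id = "n2", channel = "air_temp",
                   value = 20, flag = "ok"))
  tb <- new_series_table(dplyr::arrange(tb, node_id, channel, timestamp))
  frames <- frame_sequence(small_geom(), tb, "air_temp", period = "hourly",
                           cell_size = 5, radius = 30)
  expect_length(frames, 24)
  for (f in frames[-1]) expect_identical(f$values, frames[[1]]$values)
  expect_true(all(abs(frames[[1]]$values - 20) < 1e-12))

  f <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(frames[[1]], f)
  m <- as.matrix(utils::read.csv(f, header = FALSE))
  expect_identical(dim(m), c(length(frames[[1]]$y), length(frames[[1]]$x)))
})
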