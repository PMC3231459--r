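# Spatial layer: node layout geometry (transects, concentric-ring "star"
# deployments, grids), inverse-distance-weighted scalar fields, and the
# reliability map that accompanies every interpolated field — showing
# where the interpolation is actually supported by working sensors.

#' Deployment geometry
#'
#' Site location plus node coordinates in a local planar frame (metres,
#' x east, y north, origin at the deployment reference point) and sensor
#' mounting heights.
#'
#' @param site A [site_location()].
#' @param nodes Tibble with `node_id`, `x`, `y` (metres) and optionally
#'   `height` (metres, default 1.5).
#' @param layout_kind `"transect"`, `"star"`, `"grid"` or `"custom"`.
#' @return A `deployment_geometry` object.
#' @export
deployment_geometry <- function(site, nodes,
                                layout_kind = c("custom", "transect",
                                                "star", "grid")) {
  stopifnot(inherits(site, "site_location"))
  layout_kind <- match.arg(layout_kind)
  nodes <- as_tibble(nodes)
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)))
  if (!"height" %in% names(nodes)) nodes$height <- 1.5
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id))
    abort("Node ids must be unique.")
  if (any(!is.finite(nodes$x)) || any(!is.finite(nodes$y)))
    abort("Node coordinates must be finite.")
  structure(list(site = site, nodes = nodes, layout_kind = layout_kind),
            class = "deployment_geometry")
}

#' @export
print.deployment_geometry <- function(x, ...) {
  cat(sprintf("<deployment_geometry> %s layout, %d node(s)\n",
              x$layout_kind, nrow(x$nodes)))
  print(x$site)
  invisible(x)
}

#' Standard node layouts
#'
#' The three strategies used to distribute nodes: a linear transect
#' (monitoring gradients or ecosystem transitions), concentric
#' circumferences around a point of interest such as a flux tower
#' ("star"), and regular grids for uniform area coverage.
#'
#' @param site A [site_location()].
#' @param length Transect length, metres.
#' @param n Number of transect nodes (>= 1; evenly spaced from 0 to
#'   `length` along +x).
#' @param height Sensor mounting height for all nodes, metres.
#' @return A [deployment_geometry()].
#' @export
layout_transect <- function(site, length, n, height = 1.5) {
  if (n < 1) abort("`n` must be >= 1.")
  x <- if (n == 1) 0 else seq(0, length, length.out = n)
  deployment_geometry(site,
    tibble(node_id = sprintf("t%02d", seq_len(n)), x = x, y = 0,
           height = height),
    layout_kind = "transect")
}

#' @rdname layout_transect
#' @param ring_radii Radii of the concentric rings, metres.
#' @param ring_counts Nodes per ring (same length as `ring_radii`).
#' @export
layout_star <- function(site, ring_radii, ring_counts, height = 1.5) {
  stopifnot(length(ring_radii) == length(ring_counts))
  if (any(ring_counts < 1)) abort("Ring counts must be >= 1.")
  rows <- lapply(seq_along(ring_radii), function(r) {
    k <- ring_counts[r]
    theta <- 2 * pi * (seq_len(k) - 1) / k
    tibble(node_id = sprintf("s%d_%02d", r, seq_len(k)),
           x = ring_radii[r] * cos(theta), y = ring_radii[r] * sin(theta),
           height = height)
  })
  deployment_geometry(site, dplyr::bind_rows(rows), layout_kind = "star")
}

#' @rdname layout_transect
#' @param nrow,ncol Grid dimensions (>= 1).
#' @param spacing Distance between adjacent grid nodes, metres.
#' @export
layout_grid <- function(site, nrow, ncol, spacing, height = 1.5) {
  if (nrow < 1 || ncol < 1) abort("Grid dimensions must be >= 1.")
  g <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))
  deployment_geometry(site,
    tibble(node_id = sprintf("g%02d_%02d", g$row, g$col),
           x = (g$col - 1) * spacing, y = (g$row - 1) * spacing,
           height = height),
    layout_kind = "grid")
}

# Regular grid of cell centres covering the node bounding box (+margin).
make_grid <- function(geom, cell_size, extent = NULL, margin = 2) {
  if (is.null(extent)) {
    extent <- c(xmin = min(geom$nodes$x) - margin * cell_size,
                xmax = max(geom$nodes$x) + margin * cell_size,
                ymin = min(geom$nodes$y) - margin * cell_size,
                ymax = max(geom$nodes$y) + margin * cell_size)
  }
  xs <- seq(extent[["xmin"]] + cell_size / 2, extent[["xmax"]], by = cell_size)
  ys <- seq(extent[["ymin"]] + cell_size / 2, extent[["ymax"]], by = cell_size)
  list(x = xs, y = ys, extent = extent)
}

new_grid_raster <- function(x, y, values, reliability = NULL, cell_size,
                            bucket = NULL) {
  structure(list(x = x, y = y, values = values, reliability = reliability,
                 cell_size = cell_size, bucket = bucket),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, cell size %.1f m%s\n",
              length(x$x), length(x$y), x$cell_size,
              if (!is.null(x$bucket)) paste0(", bucket ", format(x$bucket))
              else ""))
  invisible(x)
}

#' Tidy a grid raster
#'
#' @param x A `grid_raster`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `value` and (when present)
#'   `reliability`, one row per cell.
#' @export
as_tibble.grid_raster <- function(x, ...) {
  ras <- x
  g <- expand.grid(x = ras$x, y = ras$y)
  out <- tibble(x = g$x, y = g$y, value = as.vector(ras$values))
  if (!is.null(ras$reliability)) out$reliability <- as.vector(ras$reliability)
  out
}

#' Inverse-distance-weighted field
#'
#' Interpolates point readings onto a regular grid with inverse-distance
#' weights (exponent `power`). The scheme is exact at node locations and
#' its output is a convex combination of the inputs, so it never exceeds
#' their extremes. Nodes with `NA` readings (failed or gap) are excluded;
#' with no contributing nodes at all the raster is all-`NA` (not an
#' error).
#'
#' @param geom A [deployment_geometry()].
#' @param readings Named numeric vector, node id -> value; `NA` excluded.
#' @param cell_size Grid cell size, metres.
#' @param extent Optional named vector `xmin`, `xmax`, `ymin`, `ymax`;
#'   default: node bounding box plus a two-cell margin.
#' @param power IDW exponent, default 2.
#' @return A `grid_raster` (values matrix indexed \[x, y\]).
#' @export
idw_interpolate <- function(geom, readings, cell_size, extent = NULL,
                            power = 2) {
  stopifnot(inherits(geom, "deployment_geometry"))
  grid <- make_grid(geom, cell_size, extent)
  use <- names(readings)[!is.na(readings)]
  use <- intersect(use, geom$nodes$node_id)
  vals <- matrix(NA_real_, nrow = length(grid$x), ncol = length(grid$y))
  if (length(use) > 0) {
    nd <- geom$nodes[match(use, geom$nodes$node_id), ]
    v <- as.numeric(readings[use])
    for (j in seq_along(grid$y)) {
      dx <- outer(grid$x, nd$x, "-")
      dy <- grid$y[j] - nd$y
      d2 <- sweep(dx^2, 2, dy^2, "+")
      d <- sqrt(d2)
      w <- d^(-power)
      at_node <- d < 1e-9
      for (i in seq_along(grid$x)) {
        if (any(at_node[i, ])) {
          vals[i, j] <- v[which(at_node[i, ])[1]]
        } else {
          vals[i, j] <- sum(w[i, ] * v) / sum(w[i, ])
        }
      }
    }
  }
  new_grid_raster(grid$x, grid$y, vals, cell_size = cell_size)
}

#' Sensor-coverage reliability map
#'
#' For each grid cell, reliability is the fraction of installed sensors
#' within the coverage radius that are currently working: 1 where every
#' in-range sensor reports, dropping as sensors fail, and 0 where no
#' sensor is installed within range at all. It accompanies every
#' interpolated field so readers can see how far the colour scale can be
#' trusted.
#'
#' @param geom A [deployment_geometry()].
#' @param working Named logical vector, node id -> working?
#' @param cell_size Grid cell size, metres.
#' @param radius Coverage radius, metres; default: the sensor footprint
#'   radius for each node's mounting height ([footprint_radius()]).
#' @param extent As in [idw_interpolate()].
#' @return A `grid_raster` whose `values` layer is the reliability in
#'   \[0, 1\].
#' @export
reliability_map <- function(geom, working, cell_size, radius = NULL,
                            extent = NULL) {
  stopifnot(inherits(geom, "deployment_geometry"))
  grid <- make_grid(geom, cell_size, extent)
  nd <- geom$nodes
  r <- if (is.null(radius)) footprint_radius(nd$height) else
    rep_len(radius, nrow(nd))
  if (any(r <= 0)) abort("Coverage radius must be > 0.")
  wk <- as.logical(working[nd$node_id])
  wk[is.na(wk)] <- FALSE
  rel <- matrix(0, nrow = length(grid$x), ncol = length(grid$y))
  for (j in seq_along(grid$y)) {
    for (i in seq_along(grid$x)) {
      d <- sqrt((grid$x[i] - nd$x)^2 + (grid$y[j] - nd$y)^2)
      in_range <- d <= r
      n_inst <- sum(in_range)
      rel[i, j] <- if (n_inst == 0) 0 else sum(wk & in_range) / n_inst
    }
  }
  new_grid_raster(grid$x, grid$y, rel, cell_size = cell_size)
}

#' Animation frames of an interpolated field
#'
#' Aggregates a channel per (node, bucket), then renders one raster per
#' bucket across the whole span in chronological order, each carrying
#' both the interpolated value layer and the co-registered reliability
#' layer. Buckets in which no node reports still yield a frame
#' (all-`NA` values, reliability 0), so the cadence of the animation is
#' preserved through outages.
#'
#' @param geom A [deployment_geometry()].
#' @param table A `series_table`.
#' @param channel Channel to map, e.g. `"air_temp"`.
#' @param period Aggregation bucket, `"hourly"` or `"daily"`.
#' @param cell_size Grid cell size, metres.
#' @param radius Coverage radius for the reliability layer, metres
#'   (default: per-node footprint radius).
#' @param interval_min Sampling interval of the input, minutes.
#' @param min_coverage Bucket coverage rule, as in [aggregate_series()].
#' @param power IDW exponent.
#' @return A list of `grid_raster` frames, one per bucket, in order.
#' @export
frame_sequence <- function(geom, table, channel, period = "hourly",
                           cell_size = 5, radius = NULL, interval_min = 15,
                           min_coverage = 0.75, power = 2) {
  stopifnot(inherits(geom, "deployment_geometry"),
            inherits(table, "series_table"))
  tb <- restore_series(as_tibble(table)[table$channel == channel, ], table)
  if (nrow(tb) == 0) abort(sprintf("No '%s' records in the table.", channel))
  agg <- aggregate_series(tb, period = period, statistic = "mean",
                          interval_min = interval_min,
                          min_coverage = min_coverage)
  step <- if (period == "hourly") 3600 else 86400
  buckets <- seq(min(agg$bucket), max(agg$bucket), by = step)
  extent <- make_grid(geom, cell_size)$extent
  lapply(buckets, function(b) {
    slice <- agg[agg$bucket == b & agg$flag == "ok", ]
    readings <- setNames(rep(NA_real_, nrow(geom$nodes)),
                         geom$nodes$node_id)
    readings[slice$node_id] <- slice$value
    ras <- idw_interpolate(geom, readings, cell_size, extent = extent,
                           power = power)
    rel <- reliability_map(geom, !is.na(readings), cell_size,
                           radius = radius, extent = extent)
    ras$reliability <- rel$values
    ras$bucket <- b
    ras
  })
}

#' Write a raster as a plain-text CSV matrix
#'
#' @param raster A `grid_raster`.
#' @param path Output path.
#' @param layer `"values"` or `"reliability"`.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path, layer = c("values", "reliability")) {
  layer <- match.arg(layer)
  m <- raster[[layer]]
  if (is.null(m)) abort(sprintf("Raster has no '%s' layer.", layer))
  utils::write.table(t(m)[rev(seq_along(raster$y)), , drop = FALSE],
                     path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
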