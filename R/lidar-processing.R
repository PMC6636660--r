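#' Classify ground returns with a grid-minimum filter
#'
#' Gross z outliers are first flagged `noise` by a robust median filter
#' (points farther than `noise_k` MADs from the cloud median elevation).
#' Remaining points are binned into square cells of side `cell`; the cell's
#' ground reference is the median elevation of the points within 1 m of the
#' cell minimum (the raw minimum is biased low by ranging noise), and points
#' within `z_tolerance` of that reference are classified `ground`, the rest
#' `vegetation`. With `pass_through = TRUE` an already labelled cloud is
#' returned unchanged.
#'
#' @param cloud point-cloud data.table (x, y, z, ...).
#' @param cell classification cell side, m.
#' @param z_tolerance vertical tolerance above the cell minimum, m.
#' @param noise_k MAD multiplier for the outlier filter.
#' @param pass_through keep existing labels.
#' @return the cloud with a `class` column of ground/vegetation/noise labels.
#' @export
classify_ground <- function(cloud, cell = 2, z_tolerance = 0.3,
                            noise_k = 10, pass_through = FALSE) {
  if (nrow(cloud) == 0) stop("cannot classify an empty cloud")
  if (pass_through) {
    if (is.null(cloud$class)) stop("pass_through requires a class column")
    return(cloud)
  }
  dt <- data.table::copy(data.table::as.data.table(cloud))
  med <- stats::median(dt$z)
  mad <- stats::mad(dt$z)
  is_noise <- if (mad > 0) abs(dt$z - med) > noise_k * mad else
    rep(FALSE, nrow(dt))
  if (all(is_noise)) stop("all points flagged as noise")
  dt[, class := "noise"]
  keep <- which(!is_noise)
  kp <- dt[keep]
  ref <- empty_grid_over(kp, cell)
  idx <- cell_index(ref, kp$x, kp$y)
  kd <- data.table::data.table(row = idx$row, col = idx$col, z = kp$z)
  agg <- kd[, {
    zmin <- min(z)
    list(zref = stats::median(z[z <= zmin + 1]))
  }, by = .(row, col)]
  ref$values[cbind(agg$row, agg$col)] <- agg$zref
  ref <- idw_fill(ref)
  # bilinear reference surface removes the intra-cell slope error of a
  # piecewise-constant minimum
  zsurf <- raster_bilinear(ref, kp$x, kp$y)
  dt[keep, class := ifelse(abs(kp$z - zsurf) <= z_tolerance,
                           "ground", "vegetation")]
  dt[]
}

#' Build a DEM from ground returns
#'
#' Cell value = mean elevation of the ground returns falling in the cell;
#' cells without ground returns are filled by inverse-distance weighting
#' from filled cells (see [idw_fill()]).
#'
#' @param cloud point cloud with a `class` column (only `ground` points are
#'   used) or a pre-filtered ground-only table.
#' @param pixel_size DEM cell side, m.
#' @param extent optional c(xmin, ymin, xmax, ymax); defaults to the ground
#'   point bounding box.
#' @param origin optional c(x, y) the grid is snapped to (cell edges fall on
#'   origin + i * pixel_size).
#' @return a fully filled `raster_grid` of ground elevations.
#' @export
build_dem <- function(cloud, pixel_size = 2, extent = NULL, origin = NULL) {
  dt <- data.table::as.data.table(cloud)
  if (!is.null(dt$class)) dt <- dt[class == "ground"]
  if (nrow(dt) < 3) stop("need at least 3 ground points to build a DEM")
  g <- empty_grid_over(dt, pixel_size, extent, origin)
  idx <- cell_index(g, dt$x, dt$y)
  dd <- data.table::data.table(row = idx$row, col = idx$col, z = dt$z)
  agg <- dd[, .(z = mean(z)), by = .(row, col)]
  g$values[cbind(agg$row, agg$col)] <- agg$z
  idw_fill(g)
}

# raster covering an extent, snapped to an origin
empty_grid_over <- function(dt, pixel_size, extent = NULL, origin = NULL) {
  if (is.null(extent))
    extent <- c(min(dt$x), min(dt$y), max(dt$x), max(dt$y))
  if (is.null(origin)) origin <- extent[1:2]
  x0 <- origin[1] + floor((extent[1] - origin[1]) / pixel_size) * pixel_size
  y0 <- origin[2] + floor((extent[2] - origin[2]) / pixel_size) * pixel_size
  n_cols <- max(1L, ceiling((extent[3] - x0) / pixel_size - 1e-9))
  n_rows <- max(1L, ceiling((extent[4] - y0) / pixel_size - 1e-9))
  raster_grid(c(x0, y0), pixel_size, n_rows, n_cols, NA_real_)
}

#' Normalize a point cloud to height above ground
#'
#' Subtracts the bilinearly interpolated DEM elevation from each return and
#' clamps small negative residuals to zero. Noise-classified points are
#' dropped.
#'
#' @param cloud classified point cloud.
#' @param dem DEM `raster_grid` from [build_dem()].
#' @return the cloud with a `height` column (height above ground, m),
#'   noise removed.
#' @export
normalize_heights <- function(cloud, dem) {
  dt <- data.table::as.data.table(cloud)
  if (!is.null(dt$class)) dt <- dt[class != "noise"]
  dt <- data.table::copy(dt)
  dt[, height := pmax(z - raster_bilinear(dem, x, y), 0)]
  dt[]
}

#' Rasterize a normalized point cloud into a canopy height model
#'
#' Cell value is the mean height of the vegetation returns in the cell (a
#' single return gives its own height); cells containing only ground returns
#' are 0; cells with no returns at all are filled by inverse-distance
#' weighting from filled cells.
#'
#' @param npc normalized point cloud (needs `height` and `class` columns).
#' @param pixel_size CHM cell side, m.
#' @param extent,origin see [build_dem()]. Snapping the origin to the plot
#'   grid makes a 20 m plot tile exactly into 400 cells at 1 m.
#' @param idw_power,idw_k gap-filling parameters, see [idw_fill()].
#' @return a `raster_grid` of canopy heights (>= 0).
#' @export
rasterize_chm <- function(npc, pixel_size = 1, extent = NULL, origin = NULL,
                          idw_power = 2, idw_k = 12) {
  dt <- data.table::as.data.table(npc)
  if (nrow(dt) == 0) stop("cannot rasterize an empty cloud")
  stopifnot(pixel_size > 0, !is.null(dt$height))
  g <- empty_grid_over(dt, pixel_size, extent, origin)
  idx <- cell_index(g, dt$x, dt$y)
  dd <- data.table::data.table(row = idx$row, col = idx$col,
                               h = dt$height, veg = dt$class == "vegetation")
  agg <- dd[, .(value = if (any(veg)) mean(h[veg]) else 0),
            by = .(row, col)]
  g$values[cbind(agg$row, agg$col)] <- agg$value
  idw_fill(g, power = idw_power, k = idw_k)
}

#' Top-of-canopy height of a plot
#'
#' Arithmetic mean of the CHM cells whose centres fall inside the plot
#' rectangle — for a 20 m plot on a 1 m CHM aligned to the plot grid, the
#' mean of its 400 pixels.
#'
#' @param chm CHM `raster_grid`.
#' @param plot a list/row with xmin, ymin, xmax, ymax.
#' @param cells optional precomputed [cell_centers()] table (re-used when
#'   extracting many plots from one CHM).
#' @return TCH, m.
#' @export
extract_tch <- function(chm, plot, cells = NULL) {
  if (is.null(cells)) cells <- cell_centers(chm)
  sel <- cells[x > plot$xmin & x < plot$xmax &
               y > plot$ymin & y < plot$ymax & !is.na(value) &
               value != chm$nodata]
  if (nrow(sel) == 0) stop("no CHM cells inside plot")
  mean(sel$value)
}

#' Height percentiles of canopy returns
#'
#' Linear-interpolation quantiles (type 7) of the normalized heights of
#' returns above `cutoff`.
#'
#' @param heights normalized heights, m.
#' @param levels percentile levels in (0, 100).
#' @param cutoff minimum height for a return to count as canopy, m.
#' @return named numeric (`h25`, ..., `h95`), or all-NA if no return
#'   qualifies.
#' @export
height_percentiles <- function(heights, levels = c(25, 50, 75, 90, 95),
                               cutoff = 2) {
  h <- heights[heights > cutoff]
  out <- stats::setNames(rep(NA_real_, length(levels)),
                         paste0("h", levels))
  if (length(h) == 0) return(out)
  out[] <- stats::quantile(h, probs = levels / 100, names = FALSE, type = 7)
  out
}

#' Density metrics of the return-height distribution
#'
#' `dXX` is the fraction of all returns whose normalized height exceeds
#' XX% of the plot's maximum normalized height, so d25 >= d50 >= ... >= d95
#' and each lies in (0, 1] on vegetated plots.
#'
#' @param heights normalized heights of all returns in the plot, m.
#' @param levels percentage levels of the maximum height.
#' @return named numeric (`d25`, ..., `d95`); all 0 when the maximum height
#'   is 0.
#' @export
density_percentiles <- function(heights, levels = c(25, 50, 75, 90, 95)) {
  out <- stats::setNames(rep(0, length(levels)), paste0("d", levels))
  if (length(heights) == 0) stop("plot has no returns")
  hmax <- max(heights)
  if (hmax <= 0) return(out)
  for (i in seq_along(levels))
    out[i] <- mean(heights > levels[i] / 100 * hmax)
  out
}

#' Canopy cover from first returns
#'
#' Fraction of first returns with normalized height above `cc_threshold`.
#'
#' @param npc_plot normalized point cloud of one plot (needs `height`,
#'   `return_number`).
#' @param cc_threshold height threshold, m.
#' @return fraction in [0, 1].
#' @export
canopy_cover <- function(npc_plot, cc_threshold = 2) {
  first <- npc_plot[npc_plot$return_number == 1L, ]
  if (nrow(first) == 0) stop("plot has no first returns")
  mean(first$height > cc_threshold)
}

# Assign points to plot rectangles (row index into `plots`, NA if outside).
# Containment is strict on all edges, so boundary points belong to no plot.
# When every rectangle spans exactly one interval of the break grids formed
# by the xmin/ymin values, assignment is a vectorized lookup; otherwise a
# per-plot scan is used.
rect_assign <- function(x, y, plots) {
  n <- length(x)
  pid <- rep(NA_integer_, n)
  xb <- sort(unique(plots$xmin)); yb <- sort(unique(plots$ymin))
  fast <- all(findInterval(plots$xmax - 1e-9, xb) == match(plots$xmin, xb)) &&
          all(findInterval(plots$ymax - 1e-9, yb) == match(plots$ymin, yb))
  if (fast) {
    M <- matrix(NA_integer_, nrow = length(xb), ncol = length(yb))
    M[cbind(match(plots$xmin, xb), match(plots$ymin, yb))] <-
      seq_len(nrow(plots))
    ix <- findInterval(x, xb); iy <- findInterval(y, yb)
    inb <- ix >= 1 & iy >= 1
    pid[inb] <- M[cbind(ix[inb], iy[inb])]
  } else {
    for (i in seq_len(nrow(plots))) {
      sel <- x > plots$xmin[i] & x < plots$xmax[i] &
             y > plots$ymin[i] & y < plots$ymax[i]
      pid[sel] <- i
    }
  }
  ok <- !is.na(pid)
  inside <- ok
  inside[ok] <- x[ok] > plots$xmin[pid[ok]] & x[ok] < plots$xmax[pid[ok]] &
                y[ok] > plots$ymin[pid[ok]] & y[ok] < plots$ymax[pid[ok]]
  pid[!inside] <- NA_integer_
  pid
}

#' Top-of-canopy height of every plot in one pass
#'
#' Vectorized equivalent of calling [extract_tch()] per plot: the mean of
#' the non-nodata CHM cells whose centres fall inside each rectangle. The
#' rectangles must not overlap (plots and fishnet cells never do).
#'
#' @param chm CHM `raster_grid`.
#' @param plots data.table of non-overlapping plot rectangles.
#' @param allow_empty return NA for rectangles containing no CHM cell
#'   instead of raising an error.
#' @return numeric TCH per plot row.
#' @export
tch_by_plot <- function(chm, plots, allow_empty = FALSE) {
  cells <- cell_centers(chm)
  ok <- !is.na(cells$value) & cells$value != chm$nodata
  pid <- rect_assign(cells$x, cells$y, plots)
  keep <- ok & !is.na(pid)
  sums <- tapply(cells$value[keep], factor(pid[keep],
                                           levels = seq_len(nrow(plots))),
                 mean)
  if (any(is.na(sums)) && !allow_empty)
    stop("no CHM cells inside plot(s) ",
         paste(plots$plot_id[is.na(sums)], collapse = ", "))
  as.numeric(sums)
}

#' Per-plot LiDAR predictor metrics
#'
#' Computes, for every plot rectangle, TCH from the CHM plus the
#' height-percentile, density and canopy-cover metrics from the normalized
#' point cloud.
#'
#' @param npc normalized point cloud ([normalize_heights()]).
#' @param chm CHM `raster_grid` aligned to the plot grid.
#' @param plots data.table of plot rectangles (plot_id, xmin, ymin, xmax,
#'   ymax).
#' @param cutoff canopy height cutoff for percentiles, m.
#' @param cc_threshold cover threshold, m.
#' @param allow_empty see [tch_by_plot()]; used when gridding beyond the
#'   surveyed extent.
#' @return data.table: plot_id, tch, h25..h95, d25..d95, cc, n_points.
#'   Plots whose percentile metrics are undefined carry NAs.
#' @export
plot_metrics <- function(npc, chm, plots, cutoff = 2, cc_threshold = 2,
                         allow_empty = FALSE) {
  dt <- data.table::as.data.table(npc)
  plots <- data.table::as.data.table(plots)
  tch <- tch_by_plot(chm, plots, allow_empty = allow_empty)
  pid <- rect_assign(dt$x, dt$y, plots)
  dlev <- c(25, 50, 75, 90, 95)
  per_plot <- function(i) {
    inp <- dt[which(pid == i)]
    hp <- height_percentiles(inp$height, cutoff = cutoff)
    dp <- if (nrow(inp)) density_percentiles(inp$height) else
      stats::setNames(rep(NA_real_, 5), paste0("d", dlev))
    cc <- if (nrow(inp) && any(inp$return_number == 1L))
      canopy_cover(inp, cc_threshold) else NA_real_
    data.table::data.table(plot_id = plots$plot_id[i], tch = tch[i],
                           t(hp), t(dp), cc = cc, n_points = nrow(inp))
  }
  data.table::rbindlist(lapply(seq_len(nrow(plots)), per_plot))
}

#' Join LiDAR predictors to field responses
#'
#' One row per plot with the predictor metrics and the inventory responses;
#' mismatched plot ids are an error naming the orphans.
#'
#' @param metrics output of [plot_metrics()].
#' @param summaries output of [plot_summaries()].
#' @return data.table keyed by plot_id.
#' @export
plot_metrics_table <- function(metrics, summaries) {
  m <- data.table::as.data.table(metrics)
  s <- data.table::as.data.table(summaries)
  only_m <- setdiff(m$plot_id, s$plot_id)
  only_s <- setdiff(s$plot_id, m$plot_id)
  if (length(only_m) || length(only_s))
    stop("plot id mismatch; only in metrics: ",
         paste(only_m, collapse = ", "), "; only in summaries: ",
         paste(only_s, collapse = ", "))
  out <- merge(m, s, by = "plot_id")
  data.table::setkey(out, plot_id)
  out[]
}
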