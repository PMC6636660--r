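#' Build a square fishnet over an extent
#'
#' Axis-aligned, non-overlapping cells snapped to an origin; cells clipped
#' by the extent are retained and flagged `partial` with their true area.
#'
#' @param extent c(xmin, ymin, xmax, ymax), planar metres.
#' @param cell_side cell side, m (default 20, matching the field plots).
#' @param origin c(x, y) the grid is snapped to (default the extent corner).
#' @return a `fishnet` data.table: cell_id, row, col, xmin, ymin, xmax,
#'   ymax, area_m2, partial.
#' @export
make_fishnet <- function(extent, cell_side = 20, origin = NULL) {
  stopifnot(length(extent) == 4, cell_side > 0)
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("degenerate extent")
  if (is.null(origin)) origin <- extent[1:2]
  x0 <- origin[1] + floor((extent[1] - origin[1]) / cell_side) * cell_side
  y0 <- origin[2] + floor((extent[2] - origin[2]) / cell_side) * cell_side
  ncx <- max(1L, ceiling((extent[3] - x0) / cell_side - 1e-9))
  ncy <- max(1L, ceiling((extent[4] - y0) / cell_side - 1e-9))
  cols <- x0 + (seq_len(ncx) - 1L) * cell_side
  rows <- y0 + (seq_len(ncy) - 1L) * cell_side
  net <- data.table::CJ(ymin0 = rows, xmin0 = cols)
  net[, `:=`(xmin = pmax(xmin0, extent[1]), ymin = pmax(ymin0, extent[2]),
             xmax = pmin(xmin0 + cell_side, extent[3]),
             ymax = pmin(ymin0 + cell_side, extent[4]))]
  net[, `:=`(col = as.integer(round((xmin0 - x0) / cell_side)) + 1L,
             row = as.integer(round((ymin0 - y0) / cell_side)) + 1L)]
  net[, `:=`(area_m2 = (xmax - xmin) * (ymax - ymin),
             partial = (xmax - xmin < cell_side - 1e-9) |
                       (ymax - ymin < cell_side - 1e-9))]
  net[, cell_id := seq_len(.N)]
  net[, c("xmin0", "ymin0") := NULL]
  data.table::setcolorder(net, c("cell_id", "row", "col"))
  structure(net[], cell_side = cell_side)
}

#' Predict a wall-to-wall carbon density map
#'
#' Extracts, per fishnet cell, the same LiDAR metrics used for plots (TCH
#' from the CHM; percentile metrics from the normalized cloud when the model
#' needs them) and applies the fitted model. Cells without returns get
#' nodata (NA).
#'
#' @param fit a `power_fit` on TCH, `daisy_fit` or `mlr_fit`.
#' @param npc normalized point cloud.
#' @param chm CHM `raster_grid` (aligned with the fishnet origin).
#' @param fishnet a [make_fishnet()] grid.
#' @param cutoff,cc_threshold metric parameters, see [plot_metrics()].
#' @return an `acd_map` data.table: the fishnet plus `tch` and `acd`
#'   columns; attribute `model` records the fit class.
#' @export
predict_map <- function(fit, npc, chm, fishnet, cutoff = 2,
                        cc_threshold = 2) {
  cells <- data.table::as.data.table(fishnet)
  cells <- data.table::copy(cells)
  data.table::setnames(cells, "cell_id", "plot_id")
  needs_metrics <- inherits(fit, "mlr_fit")
  met <- plot_metrics(npc, chm, cells, cutoff = cutoff,
                      cc_threshold = cc_threshold, allow_empty = TRUE)
  out <- data.table::copy(data.table::as.data.table(fishnet))
  out[, tch := met$tch]
  acd <- rep(NA_real_, nrow(out))
  valid <- met$n_points > 0 & is.finite(met$tch)
  if (needs_metrics) {
    ok <- valid
    for (p in fit$predictors) ok <- ok & is.finite(met[[p]]) & met[[p]] > 0
    acd[ok] <- predict_acd(fit, as.data.frame(met[ok]))
  } else if (inherits(fit, "daisy_fit")) {
    ok <- valid & met$tch > 0
    acd[ok] <- predict_acd(fit, met$tch[ok])
  } else if (inherits(fit, "power_fit")) {
    ok <- valid & met$tch > 0
    acd[ok] <- predict_acd(fit, met$tch[ok])
  } else stop("unsupported model class: ", paste(class(fit), collapse = "/"))
  out[, acd := acd]
  structure(out[], cell_side = attr(fishnet, "cell_side"),
            model = class(fit)[1])
}

#' Summarise a carbon density map
#'
#' Mean and maximum cell ACD, total carbon stock (sum of density times true
#' cell area in hectares) and the share of valid cells per density class.
#'
#' @param map an `acd_map` from [predict_map()].
#' @param class_breaks optional increasing breaks (Mg C ha^-1) for the
#'   density classes; default = quintiles of the mapped values.
#' @return list(mean_acd, max_acd, total_carbon_mg, n_cells, n_valid,
#'   class_percentages).
#' @export
summarize_map <- function(map, class_breaks = NULL) {
  v <- map$acd
  ok <- is.finite(v)
  if (!any(ok)) stop("map has no valid cells")
  area_ha <- map$area_m2 / 1e4
  if (is.null(class_breaks))
    class_breaks <- unique(stats::quantile(v[ok], probs = seq(0, 1, 0.2)))
  cls <- cut(v[ok], breaks = class_breaks, include.lowest = TRUE)
  list(mean_acd = mean(v[ok]),
       max_acd = max(v[ok]),
       total_carbon_mg = sum(v[ok] * area_ha[ok]),
       n_cells = nrow(map), n_valid = sum(ok),
       class_percentages = as.numeric(table(cls)) / sum(ok))
}

#' Compare two carbon density maps on the same fishnet
#'
#' @param m1,m2 `acd_map`s on an identical fishnet.
#' @return list(diff — the fishnet with `acd_diff = m1 - m2`,
#'   relative_total_diff — |T1 - T2| / T1 on total stocks).
#' @export
compare_maps <- function(m1, m2) {
  if (nrow(m1) != nrow(m2) ||
      !isTRUE(all.equal(m1$xmin, m2$xmin)) ||
      !isTRUE(all.equal(m1$ymin, m2$ymin)))
    stop("maps are not on the same fishnet")
  d <- data.table::as.data.table(m1)[, .(cell_id, row, col, xmin, ymin)]
  d[, acd_diff := m1$acd - m2$acd]
  t1 <- summarize_map(m1)$total_carbon_mg
  t2 <- summarize_map(m2)$total_carbon_mg
  list(diff = d[], relative_total_diff = abs(t1 - t2) / t1)
}

#' Sensitivity of the TCH model to CHM pixel size
#'
#' For each pixel size, rebuilds the CHM from the normalized cloud,
#' re-extracts per-plot TCH, refits the power-law ACD model and records its
#' goodness of fit. Coarser pixels blur canopy gaps into vegetated cells, so
#' TCH loses the cover signal and the fit degrades.
#'
#' @param npc normalized point cloud.
#' @param plots plot rectangles (plot_id, xmin, ymin, xmax, ymax).
#' @param acd per-plot carbon densities aligned with `plots`.
#' @param sizes CHM pixel sizes to test, m; all must be <= the plot side.
#' @param origin CHM snap origin (default plot-grid corner).
#' @return data.table: pixel_size, r2, rmse_back.
#' @export
pixel_size_experiment <- function(npc, plots, acd, sizes = 1:10,
                                  origin = NULL) {
  side <- min(plots$xmax - plots$xmin)
  if (any(sizes > side))
    stop("pixel size exceeds the plot side (", side, " m)")
  if (is.null(origin)) origin <- c(min(plots$xmin), min(plots$ymin))
  extent <- c(min(plots$xmin), min(plots$ymin),
              max(plots$xmax), max(plots$ymax))
  res <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    chm <- rasterize_chm(npc, pixel_size = sizes[i], extent = extent,
                         origin = origin)
    tch <- tch_by_plot(chm, data.table::as.data.table(plots))
    fit <- fit_power(tch, acd, xname = "TCH")
    res[[i]] <- data.table::data.table(pixel_size = sizes[i],
                                       r2 = fit$r2,
                                       rmse_back = fit$rmse_back)
  }
  data.table::rbindlist(res)
}

#' Write an ACD map as CSV
#'
#' Plain-text export (row, col, centre coordinates, tch, acd).
#'
#' @param map an `acd_map`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_acd_map <- function(map, path) {
  out <- data.table::as.data.table(map)[
    , .(row, col, x = (xmin + xmax) / 2, y = (ymin + ymax) / 2, tch, acd)]
  data.table::fwrite(out, path)
  invisible(path)
}
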