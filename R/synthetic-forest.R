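# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration of a synthetic spruce stand
#'
#' Describes a campaign of square inventory plots of pure spruce. Defaults
#' emulate the mountain spruce campaign the package is designed around:
#' 94 plots of 20 m x 20 m, about 61 census trees (DBH >= 5 cm) per plot,
#' a right-skewed Weibull DBH distribution, and a power-law height-diameter
#' curve `H = 1.3 + h_a * D^h_b * exp(eps)` with lognormal scatter.
#'
#' @param n_plots number of square plots.
#' @param plot_side plot side length, m.
#' @param stems_per_plot integer range (min, max) of census stems per plot;
#'   counts are drawn uniformly.
#' @param dbh_weibull Weibull (shape, scale) for DBH in cm, left-truncated at
#'   the 5 cm census threshold; the untruncated distribution must place > 90%
#'   of its mass above 5 cm so the truncation is mild.
#' @param plot_scale_sd sd of the lognormal per-plot multiplier applied to
#'   the Weibull scale, emulating stand-stage/site variation between plots
#'   (plots of an uneven-aged campaign differ in typical tree size, not just
#'   stem count).
#' @param height_curve numeric (h_a, h_b, sigma_h) of the height-diameter
#'   curve; `sigma_h` is the sd of the multiplicative log-scale noise.
#' @param top_damage base probability of a broken or dieback top; the
#'   per-tree probability scales with the cubed size ratio
#'   `(D / scale)^3` (capped at 0.5), since top breakage concentrates in
#'   the oldest, largest stems of natural stands. A damaged tree keeps its
#'   DBH but its height is reduced to 55-85% of the intact value.
#' @param crown_ratio fraction of tree height occupied by live crown.
#' @param crown_radius_coef crown radius per unit DBH, m per cm.
#' @param terrain numeric (mean elevation m, relief amplitude m) of the
#'   smooth analytic terrain surface.
#' @param rng_seed integer seed; identical seeds give identical stands.
#' @return a `stand_config` list.
#' @export
stand_config <- function(n_plots = 94L,
                         plot_side = 20,
                         stems_per_plot = c(46L, 76L),
                         dbh_weibull = c(shape = 2.0, scale = 16),
                         plot_scale_sd = 0.15,
                         height_curve = c(h_a = 1.7, h_b = 0.55,
                                          sigma_h = 0.25),
                         top_damage = 0.06,
                         crown_ratio = 0.6,
                         crown_radius_coef = 0.08,
                         terrain = c(mean = 2800, amplitude = 5),
                         rng_seed = 1L) {
  stopifnot(n_plots >= 1, plot_side > 0,
            length(stems_per_plot) == 2, stems_per_plot[1] >= 1,
            stems_per_plot[2] >= stems_per_plot[1],
            length(dbh_weibull) == 2, length(height_curve) == 3,
            height_curve[3] >= 0, plot_scale_sd >= 0,
            top_damage >= 0, top_damage <= 1,
            crown_ratio > 0, crown_ratio < 1,
            crown_radius_coef > 0, length(terrain) == 2)
  if (any(dbh_weibull <= 0))
    stop("invalid Weibull parameters: shape and scale must be positive")
  p5 <- stats::pweibull(5, shape = dbh_weibull[1], scale = dbh_weibull[2],
                        lower.tail = FALSE)
  if (p5 <= 0.9)
    stop(sprintf(paste("dbh_weibull places only %.1f%% of mass above the 5 cm",
                       "census threshold (need > 90%%)"), 100 * p5))
  structure(list(
    n_plots = as.integer(n_plots), plot_side = plot_side,
    stems_per_plot = as.integer(stems_per_plot),
    dbh_weibull = unname(dbh_weibull), plot_scale_sd = plot_scale_sd,
    height_curve = unname(height_curve), top_damage = top_damage,
    crown_ratio = crown_ratio, crown_radius_coef = crown_radius_coef,
    terrain = unname(terrain), rng_seed = as.integer(rng_seed)),
    class = "stand_config")
}

#' Configuration of the discrete-return LiDAR simulator
#'
#' @param pulse_density laser pulses per m^2 (default 3.43, the merged
#'   multi-pass density the simulator emulates).
#' @param ground_penetration probability that a pulse intercepted by canopy
#'   still produces a ground echo.
#' @param vertical_noise_sd Gaussian ranging noise sd, m.
#' @param max_returns_per_pulse upper bound on echoes per pulse (1-5; the
#'   simulator's first-surface model emits at most 2).
#' @param noise_fraction fraction of pulses that also yield a gross z outlier
#'   labelled `noise`, to exercise filtering.
#' @param rng_seed integer seed.
#' @return a `lidar_sim_config` list.
#' @export
lidar_sim_config <- function(pulse_density = 3.43,
                             ground_penetration = 0.5,
                             vertical_noise_sd = 0.15,
                             max_returns_per_pulse = 2L,
                             noise_fraction = 0.002,
                             rng_seed = 1L) {
  if (pulse_density <= 0) stop("pulse_density must be positive")
  stopifnot(ground_penetration >= 0, ground_penetration <= 1,
            vertical_noise_sd >= 0,
            max_returns_per_pulse >= 1, max_returns_per_pulse <= 5,
            noise_fraction >= 0, noise_fraction < 1)
  structure(list(
    pulse_density = pulse_density, ground_penetration = ground_penetration,
    vertical_noise_sd = vertical_noise_sd,
    max_returns_per_pulse = as.integer(max_returns_per_pulse),
    noise_fraction = noise_fraction, rng_seed = as.integer(rng_seed)),
    class = "lidar_sim_config")
}

#' Terrain elevation of the analytic ground surface
#'
#' Smooth doubly periodic relief used by the simulator:
#' `mean + amplitude * sin(x / 41) * cos(y / 59)`.
#'
#' @param x,y coordinates, m.
#' @param terrain numeric (mean elevation, amplitude).
#' @return elevations, m.
#' @export
terrain_elevation <- function(x, y, terrain = c(2800, 5)) {
  terrain[1] + terrain[2] * sin(x / 41) * cos(y / 59)
}

#' Generate a synthetic spruce stand
#'
#' Lays plots out contiguously on a square grid starting at the origin, draws
#' a uniform stem count per plot, DBH from the truncated Weibull, height from
#' the height-diameter curve, and uniform tree positions with a minimum
#' spacing of 0.8 m (rejection sampling). Crown base and radius follow the
#' configured crown ratio and radius coefficient.
#'
#' @param config a [stand_config()].
#' @return list with `trees` (data.table: plot_id, x, y, dbh, height,
#'   crown_base, crown_radius), `plots` (data.table: plot_id, xmin, ymin,
#'   xmax, ymax) and the `config`.
#' @export
generate_stand <- function(config = stand_config()) {
  stopifnot(inherits(config, "stand_config"))
  side <- config$plot_side
  ncols <- ceiling(sqrt(config$n_plots))
  plots <- data.table::data.table(plot_id = seq_len(config$n_plots))
  plots[, `:=`(xmin = ((plot_id - 1L) %% ncols) * side,
               ymin = ((plot_id - 1L) %/% ncols) * side)]
  plots[, `:=`(xmax = xmin + side, ymax = ymin + side)]

  shape <- config$dbh_weibull[1]; scale <- config$dbh_weibull[2]
  h_a <- config$height_curve[1]; h_b <- config$height_curve[2]
  sigma_h <- config$height_curve[3]

  trees <- with_seed(config$rng_seed, {
    counts <- sample(config$stems_per_plot[1]:config$stems_per_plot[2],
                     config$n_plots, replace = TRUE)
    # per-plot stand-stage multiplier on typical tree size
    plot_scale <- scale * exp(stats::rnorm(config$n_plots, 0,
                                           config$plot_scale_sd))
    res <- vector("list", config$n_plots)
    for (i in seq_len(config$n_plots)) {
      n <- counts[i]
      # truncated Weibull via inverse CDF on [F(5), 1)
      p5 <- stats::pweibull(5, shape, plot_scale[i])
      u <- p5 + stats::runif(n) * (1 - p5)
      dbh <- stats::qweibull(u, shape, plot_scale[i])
      height <- 1.3 + h_a * dbh^h_b * exp(stats::rnorm(n, 0, sigma_h))
      if (config$top_damage > 0) {
        p_dam <- pmin(0.5, config$top_damage * (dbh / scale)^3)
        dam <- stats::runif(n) < p_dam
        height[dam] <- pmax(1.31, height[dam] *
                              stats::runif(sum(dam), 0.55, 0.85))
      }
      x <- numeric(n); y <- numeric(n)
      for (j in seq_len(n)) {
        for (try in 1:50) {
          px <- stats::runif(1, plots$xmin[i], plots$xmax[i])
          py <- stats::runif(1, plots$ymin[i], plots$ymax[i])
          if (j == 1L ||
              min((x[1:(j - 1)] - px)^2 + (y[1:(j - 1)] - py)^2) > 0.8^2)
            break
        }
        x[j] <- px; y[j] <- py
      }
      res[[i]] <- data.table::data.table(
        plot_id = plots$plot_id[i], x = x, y = y, dbh = dbh, height = height,
        crown_base = height * (1 - config$crown_ratio),
        crown_radius = config$crown_radius_coef * dbh)
    }
    data.table::rbindlist(res)
  })
  list(trees = trees, plots = plots, config = config)
}

#' Simulate a discrete-return LiDAR survey over a stand
#'
#' Pulses are placed on a jittered square grid at the configured density over
#' the stand extent (plus a small buffer). Each vertical pulse is intersected
#' with the conical crown surfaces (apex at the tree top, base radius
#' `crown_radius` at `crown_base`) and the analytic terrain; the highest
#' intersected surface yields the first return, plus Gaussian ranging noise.
#' A canopy-intercepted pulse also emits a ground echo with probability
#' `ground_penetration`. A small fraction of pulses additionally emit a gross
#' outlier labelled `noise`.
#'
#' @param stand result of [generate_stand()].
#' @param config a [lidar_sim_config()].
#' @param buffer extra margin (m) around the plot extent covered by pulses.
#' @return data.table point cloud: x, y, z (elevation m), return_number,
#'   n_returns, class ("ground", "vegetation" or "noise").
#' @export
simulate_point_cloud <- function(stand, config = lidar_sim_config(),
                                 buffer = 2) {
  stopifnot(inherits(config, "lidar_sim_config"))
  plots <- stand$plots
  if (nrow(plots) == 0) stop("empty stand extent")
  xr <- c(min(plots$xmin) - buffer, max(plots$xmax) + buffer)
  yr <- c(min(plots$ymin) - buffer, max(plots$ymax) + buffer)
  if (diff(xr) <= 0 || diff(yr) <= 0) stop("empty stand extent")
  spacing <- 1 / sqrt(config$pulse_density)
  terrain <- stand$config$terrain

  with_seed(config$rng_seed, {
    gx <- seq(xr[1] + spacing / 2, xr[2], by = spacing)
    gy <- seq(yr[1] + spacing / 2, yr[2], by = spacing)
    pulses <- data.table::CJ(px = gx, py = gy)
    n <- nrow(pulses)
    pulses[, `:=`(px = px + stats::runif(n, -spacing / 2, spacing / 2),
                  py = py + stats::runif(n, -spacing / 2, spacing / 2))]
    veg_z <- rep(-Inf, n)

    trees <- stand$trees
    if (nrow(trees)) {
      tree_ground <- terrain_elevation(trees$x, trees$y, terrain)
      apex <- tree_ground + trees$height
      crown_depth <- trees$height - trees$crown_base
      tplot <- split(seq_len(nrow(trees)), trees$plot_id)
      for (pid in names(tplot)) {
        ti <- tplot[[pid]]
        pr <- plots[plot_id == as.integer(pid)]
        rmax <- max(trees$crown_radius[ti])
        pi_idx <- which(pulses$px >= pr$xmin - rmax & pulses$px <= pr$xmax + rmax &
                        pulses$py >= pr$ymin - rmax & pulses$py <= pr$ymax + rmax)
        if (!length(pi_idx)) next
        dx <- outer(pulses$px[pi_idx], trees$x[ti], "-")
        dy <- outer(pulses$py[pi_idx], trees$y[ti], "-")
        r <- sqrt(dx * dx + dy * dy)
        surf <- sweep(-r * rep(crown_depth[ti] / trees$crown_radius[ti],
                               each = length(pi_idx)) , 2,
                      apex[ti], "+")
        surf[r > rep(trees$crown_radius[ti], each = length(pi_idx))] <- -Inf
        dim(surf) <- c(length(pi_idx), length(ti))
        best <- max.col(surf, ties.method = "first")
        cand <- surf[cbind(seq_along(pi_idx), best)]
        veg_z[pi_idx] <- pmax(veg_z[pi_idx], cand)
      }
    }

    gz <- terrain_elevation(pulses$px, pulses$py, terrain)
    hit <- veg_z > gz + 0.05
    sd <- config$vertical_noise_sd

    first <- data.table::data.table(
      x = pulses$px, y = pulses$py,
      z = ifelse(hit, veg_z, gz) + stats::rnorm(n, 0, sd),
      return_number = 1L, n_returns = 1L,
      class = ifelse(hit, "vegetation", "ground"))
    pen <- hit & config$max_returns_per_pulse >= 2L &
      stats::runif(n) < config$ground_penetration
    first[pen, n_returns := 2L]
    second <- data.table::data.table(
      x = pulses$px[pen], y = pulses$py[pen],
      z = gz[pen] + stats::rnorm(sum(pen), 0, sd),
      return_number = 2L, n_returns = 2L, class = "ground")

    noisy <- stats::runif(n) < config$noise_fraction
    noise <- data.table::data.table(
      x = pulses$px[noisy], y = pulses$py[noisy],
      z = gz[noisy] + sample(c(-1, 1), sum(noisy), replace = TRUE) *
        stats::runif(sum(noisy), 30, 80),
      return_number = 1L, n_returns = 1L, class = "noise")

    cloud <- data.table::rbindlist(list(first, second, noise))
    data.table::setorder(cloud, x, y, return_number)
    cloud[]
  })
}

#' Read and write point clouds as plain-text tables
#'
#' Tab-separated table with header `x y z return_number n_returns class`.
#' The class column accepts the labels ground/vegetation/noise or the usual
#' LAS classification codes 2, 5 and 7. Round-trip preserves coordinates to
#' the stored precision and return numbers/labels exactly.
#'
#' @param cloud a point-cloud data.table.
#' @param path file path.
#' @param digits decimal digits stored for coordinates.
#' @return `read_points` returns a point-cloud data.table; `write_points`
#'   returns `path` invisibly.
#' @export
write_points <- function(cloud, path, digits = 3) {
  out <- data.table::data.table(
    x = round(cloud$x, digits), y = round(cloud$y, digits),
    z = round(cloud$z, digits),
    return_number = cloud$return_number, n_returns = cloud$n_returns,
    class = cloud$class)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = "class"))
  need <- c("x", "y", "z", "return_number", "n_returns", "class")
  if (!all(need %in% names(dt)))
    stop("point file must have columns ", paste(need, collapse = ", "))
  if (nrow(dt) == 0)
    return(data.table::data.table(
      x = numeric(), y = numeric(), z = numeric(),
      return_number = integer(), n_returns = integer(),
      class = character()))
  for (col in c("x", "y", "z")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric %s value at data line %d of %s",
                   col, bad, path))
    }
  }
  las_codes <- c(`2` = "ground", `5` = "vegetation", `7` = "noise")
  if (all(dt$class %in% names(las_codes)))
    dt[, class := las_codes[class]]
  ok <- dt$class %in% c("ground", "vegetation", "noise")
  if (!all(ok))
    stop("unknown class label at data line ", which(!ok)[1], " of ", path)
  validate_point_cloud(dt)
  dt[]
}

# shared structural checks on a point-cloud table
validate_point_cloud <- function(cloud) {
  stopifnot(all(c("x", "y", "z", "return_number", "n_returns", "class")
                %in% names(cloud)))
  if (nrow(cloud) == 0) return(invisible(cloud))
  if (any(!is.finite(cloud$x) | !is.finite(cloud$y) | !is.finite(cloud$z)))
    stop("non-finite coordinates in point cloud")
  if (any(cloud$return_number < 1 | cloud$return_number > cloud$n_returns))
    stop("return_number must lie in [1, n_returns]")
  invisible(cloud)
}
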