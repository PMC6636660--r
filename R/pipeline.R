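#' Configuration of a full synthetic-campaign run
#'
#' One master seed is fanned out deterministically to the stand generator,
#' the LiDAR simulator and the cross-validation shuffles, so stages can be
#' rerun independently yet reproducibly.
#'
#' @param seed master integer seed.
#' @param stand a [stand_config()]; its `rng_seed` is overridden from
#'   `seed`.
#' @param lidar a [lidar_sim_config()]; its `rng_seed` is overridden from
#'   `seed`.
#' @param pixel_size CHM pixel size for the main analysis, m.
#' @param dem_pixel_size DEM pixel size, m.
#' @param cutoff,cc_threshold metric parameters, m.
#' @param k_folds folds for cross-validated R^2.
#' @param alpha retention threshold of the percentile model.
#' @param sensitivity_sizes CHM pixel sizes for the sensitivity experiment.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       stand = stand_config(),
                       lidar = lidar_sim_config(),
                       pixel_size = 1,
                       dem_pixel_size = 2,
                       cutoff = 2,
                       cc_threshold = 2,
                       k_folds = 10L,
                       alpha = 0.05,
                       sensitivity_sizes = 1:10) {
  stand$rng_seed <- as.integer(seed)
  lidar$rng_seed <- as.integer(seed) + 1000L
  structure(list(seed = as.integer(seed), stand = stand, lidar = lidar,
                 pixel_size = pixel_size, dem_pixel_size = dem_pixel_size,
                 cutoff = cutoff, cc_threshold = cc_threshold,
                 k_folds = as.integer(k_folds), alpha = alpha,
                 sensitivity_sizes = sensitivity_sizes),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `stand` and `lidar`
#' are nested maps passed to their constructors.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$stand)) args$stand <- do.call(stand_config, y$stand)
  if (!is.null(y$lidar)) args$lidar <- do.call(lidar_sim_config, y$lidar)
  for (k in c("seed", "pixel_size", "dem_pixel_size", "cutoff",
              "cc_threshold", "k_folds", "alpha", "sensitivity_sizes"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

#' Simulate one campaign and compute the plot table
#'
#' Convenience wrapper chaining stand generation, LiDAR simulation, ground
#' classification, DEM and CHM construction, metric extraction and the
#' inventory summaries into the joined per-plot analysis table.
#'
#' @param config a [run_config()].
#' @return list: stand, cloud, dem, chm, table (plot metrics + responses).
#' @export
simulate_campaign <- function(config = run_config()) {
  stand <- generate_stand(config$stand)
  cloud <- simulate_point_cloud(stand, config$lidar)
  cloud <- classify_ground(cloud)
  extent <- c(min(stand$plots$xmin), min(stand$plots$ymin),
              max(stand$plots$xmax), max(stand$plots$ymax))
  dem <- build_dem(cloud, pixel_size = config$dem_pixel_size,
                   extent = extent, origin = extent[1:2])
  npc <- normalize_heights(cloud, dem)
  chm <- rasterize_chm(npc, pixel_size = config$pixel_size,
                       extent = extent, origin = extent[1:2])
  metrics <- plot_metrics(npc, chm, stand$plots, cutoff = config$cutoff,
                          cc_threshold = config$cc_threshold)
  summaries <- plot_summaries(stand$trees,
                              plot_area = config$stand$plot_side^2)
  list(stand = stand, cloud = cloud, npc = npc, dem = dem, chm = chm,
       table = plot_metrics_table(metrics, summaries))
}

#' Run the full analysis pipeline and write a report
#'
#' Chains simulate, inventory, metrics, model fitting (plot power models on
#' AvgH / LorH / BA, TCH power model, daisy chain, percentile MLR),
#' wall-to-wall mapping with the TCH and percentile models, map comparison,
#' and the CHM pixel-size sensitivity experiment. Rerunning with the same
#' configuration gives a byte-identical report.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created, with a warning, when
#'   missing); the JSON and text reports, plot table, maps and sensitivity
#'   table are written there.
#' @return the report list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  sim <- simulate_campaign(config)
  tb <- sim$table
  k <- config$k_folds

  fits <- list(
    avgh = fit_power(tb$avg_height, tb$acd, xname = "AvgH",
                     cv_k = k, cv_seed = config$seed + 11L),
    lorh = fit_power(tb$lorey_height, tb$acd, xname = "LorH",
                     cv_k = k, cv_seed = config$seed + 12L),
    ba   = fit_power(tb$basal_area, tb$acd, xname = "BA",
                     cv_k = k, cv_seed = config$seed + 13L),
    tch  = fit_power(tb$tch, tb$acd, xname = "TCH",
                     cv_k = k, cv_seed = config$seed + 14L),
    daisy = fit_daisy_chain(tb$tch, tb$basal_area, tb$acd,
                            cv_k = k, cv_seed = config$seed + 15L),
    mlr  = suppressWarnings(
      fit_percentile_mlr(tb, tb$acd, alpha = config$alpha,
                         cv_k = k, cv_seed = config$seed + 16L)))

  extent <- c(min(sim$stand$plots$xmin), min(sim$stand$plots$ymin),
              max(sim$stand$plots$xmax), max(sim$stand$plots$ymax))
  net <- make_fishnet(extent, cell_side = sim$stand$config$plot_side,
                      origin = extent[1:2])
  map_tch <- predict_map(fits$tch, sim$npc, sim$chm, net,
                         cutoff = config$cutoff,
                         cc_threshold = config$cc_threshold)
  map_mlr <- predict_map(fits$mlr, sim$npc, sim$chm, net,
                         cutoff = config$cutoff,
                         cc_threshold = config$cc_threshold)
  cmp <- compare_maps(map_tch, map_mlr)

  sens <- pixel_size_experiment(sim$npc, sim$stand$plots, sim$table$acd,
                                sizes = config$sensitivity_sizes,
                                origin = extent[1:2])

  fit_report <- function(f) {
    base <- list(r2 = f$r2, cv_r2 = f$cv_r2, n = f$n)
    if (inherits(f, "power_fit"))
      c(list(model = paste0("ACD = a ", f$xname, "^b"),
             a = f$a, b = f$b, rmse = f$rmse_back), base)
    else if (inherits(f, "daisy_fit"))
      c(list(model = "ACD = a BA'^b1 TCH^b2",
             link_a = f$link$a, link_b = f$link$b, link_r2 = f$link$r2,
             a = f$a, b1 = f$b1, b2 = f$b2, rmse = f$rmse_back), base)
    else
      c(list(model = "ln ACD = b0 + sum b_j ln m_j",
             predictors = f$predictors,
             coefficients = as.list(f$coefficients),
             rmse = f$rmse_back), base)
  }

  report <- list(
    seed = config$seed,
    n_plots = nrow(tb),
    n_trees = nrow(sim$stand$trees),
    n_points = nrow(sim$cloud),
    models = lapply(fits, fit_report),
    map_tch = summarize_map(map_tch),
    map_mlr = summarize_map(map_mlr),
    relative_total_diff = cmp$relative_total_diff,
    sensitivity = as.data.frame(sens))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      warning("creating missing output directory ", out_dir)
      dir.create(out_dir, recursive = TRUE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
    data.table::fwrite(tb, file.path(out_dir, "plot_table.csv"))
    write_acd_map(map_tch, file.path(out_dir, "acd_map_tch.csv"))
    write_acd_map(map_mlr, file.path(out_dir, "acd_map_mlr.csv"))
    data.table::fwrite(sens, file.path(out_dir, "pixel_sensitivity.csv"))
    return(invisible(report))
  }
  report
}

format_report <- function(rep) {
  ln <- c(
    sprintf("canopycarbon pipeline report (seed %d)", rep$seed),
    sprintf("plots: %d   trees: %d   lidar returns: %d",
            rep$n_plots, rep$n_trees, rep$n_points),
    "",
    "model fits (R2 on log scale, RMSE back-transformed):")
  for (nm in names(rep$models)) {
    m <- rep$models[[nm]]
    ln <- c(ln, sprintf("  %-5s %-22s R2 = %.4f  cvR2 = %.4f  RMSE = %.4f",
                        nm, m$model, m$r2, m$cv_r2, m$rmse))
  }
  ln <- c(ln, "",
    sprintf("TCH map:  mean %.2f  max %.2f Mg C/ha  total %.2f Mg (%d cells)",
            rep$map_tch$mean_acd, rep$map_tch$max_acd,
            rep$map_tch$total_carbon_mg, rep$map_tch$n_valid),
    sprintf("MLR map:  mean %.2f  max %.2f Mg C/ha  total %.2f Mg (%d cells)",
            rep$map_mlr$mean_acd, rep$map_mlr$max_acd,
            rep$map_mlr$total_carbon_mg, rep$map_mlr$n_valid),
    sprintf("relative total difference: %.2f%%",
            100 * rep$relative_total_diff),
    "",
    "CHM pixel-size sensitivity of the TCH model:")
  for (i in seq_len(nrow(rep$sensitivity)))
    ln <- c(ln, sprintf("  %2g m  R2 = %.4f  RMSE = %.4f",
                        rep$sensitivity$pixel_size[i],
                        rep$sensitivity$r2[i],
                        rep$sensitivity$rmse_back[i]))
  ln
}
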