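make_npc <- function(x, y, height, class = "vegetation",
                     return_number = 1L) {
  data.table::data.table(x = x, y = y, z = height, height = height,
                         return_number = return_number,
                         n_returns = return_number, class = class)
}

test_that("ground classification recovers a flat scene and honours pass-through", {
  st <- treeless_stand()
  cl <- simulate_point_cloud(st, lidar_sim_config(vertical_noise_sd = 0,
                                                  noise_fraction = 0,
                                                  rng_seed = 1))
  got <- classify_ground(cl[, !"class"])
  expect_true(all(got$class == "ground"))

  labelled <- data.table::copy(cl)
  labelled[1:5, class := "vegetation"]
  expect_identical(classify_ground(labelled, pass_through = TRUE), labelled)
  expect_error(classify_ground(cl[0]), "empty")
})

test_that("ground classification reaches 95% precision and recall on simulated stands", {
  st <- generate_stand(small_stand(seed = 12))
  cl <- simulate_point_cloud(st, lidar_sim_config(rng_seed = 13))
  truth <- cl$class
  got <- classify_ground(cl[, !"class"], cell = 2, z_tolerance = 0.3)$class
  tp <- sum(got == "ground" & truth == "ground")
  expect_gt(tp / sum(got == "ground"), 0.95)   # precision
  expect_gt(tp / sum(truth == "ground"), 0.95) # recall
  # the gross z outliers are caught by the median filter
  expect_gt(sum(got == "noise" & truth == "noise") /
            max(1, sum(truth == "noise")), 0.9)
})

test_that("DEM and normalization recover planar terrain", {
  set.seed(3)
  n <- 4000
  x <- runif(n, 0, 50); y <- runif(n, 0, 50)
  flat <- data.table::data.table(x = x, y = y, z = 100,
                                 return_number = 1L, n_returns = 1L,
                                 class = "ground")
  dem <- build_dem(flat, pixel_size = 2)
  expect_equal(as.numeric(dem$values),
               rep(100, length(dem$values)), tolerance = 1e-12)
  npc <- normalize_heights(flat, dem)
  expect_equal(npc$height, rep(0, n), tolerance = 1e-12)

  # tilted plane: vegetation offsets survive normalization
  tilt <- data.table::copy(flat)[, z := 100 + 0.1 * x]
  veg <- data.table::data.table(x = runif(500, 5, 45), y = runif(500, 5, 45),
                                return_number = 1L, n_returns = 1L,
                                class = "vegetation")
  veg[, z := 100 + 0.1 * x + 7.5]
  dem2 <- build_dem(tilt, pixel_size = 2)
  npc2 <- normalize_heights(veg, dem2)
  expect_equal(npc2$height, rep(7.5, 500), tolerance = 0.2)
  expect_error(build_dem(flat[1:2]), "3 ground points")
})

test_that("CHM rasterization follows the single/mean/IDW pixel rules", {
  npc <- make_npc(x = c(0.5, 2.5, 2.6), y = c(0.5, 0.5, 0.5),
                  height = c(12.5, 10, 20))
  chm <- rasterize_chm(npc, pixel_size = 1, extent = c(0, 0, 3, 1),
                       origin = c(0, 0))
  expect_equal(chm$values[1, 1], 12.5)   # single point keeps its height
  expect_equal(chm$values[1, 3], 15)     # two points average
  # the empty middle cell is IDW-filled from the two filled cell centres,
  # both one pixel away
  expect_equal(chm$values[1, 2], (12.5 + 15) / 2, tolerance = 1e-12)

  # ground-only cells are zero canopy, not gaps
  g <- make_npc(1.5, 0.5, 0, class = "ground")
  chm2 <- rasterize_chm(rbind(npc, g), pixel_size = 1,
                        extent = c(0, 0, 3, 1), origin = c(0, 0))
  expect_equal(chm2$values[1, 2], 0)
})

test_that("TCH equals the in-plot pixel mean", {
  g <- raster_grid(c(0, 0), 1, 20, 20, values = matrix(10, 20, 20))
  plot <- list(xmin = 0, ymin = 0, xmax = 20, ymax = 20)
  expect_equal(extract_tch(g, plot), 10)

  cb <- outer(1:20, 1:20, function(r, c) ifelse((r + c) %% 2 == 0, 0, 10))
  expect_equal(extract_tch(raster_grid(c(0, 0), 1, 20, 20, cb), plot), 5)

  set.seed(14)
  rv <- matrix(runif(400, 0, 25), 20, 20)
  rg <- raster_grid(c(0, 0), 1, 20, 20, rv)
  sub <- list(xmin = 3, ymin = 5, xmax = 11, ymax = 16)
  acc <- c()
  for (r in 1:20) for (c in 1:20) {
    cx <- c - 0.5; cy <- r - 0.5
    if (cx > 3 && cx < 11 && cy > 5 && cy < 16) acc <- c(acc, rv[r, c])
  }
  expect_equal(extract_tch(rg, sub), mean(acc), tolerance = 1e-12)
  # vectorized extraction over disjoint rectangles equals per-plot calls
  two <- data.table::data.table(plot_id = 1:2, xmin = c(3, 12),
                                ymin = c(5, 1), xmax = c(11, 19),
                                ymax = c(16, 9))
  expect_equal(tch_by_plot(rg, two),
               c(extract_tch(rg, two[1]), extract_tch(rg, two[2])),
               tolerance = 1e-12)
  expect_equal(tch_by_plot(rg, two)[1], mean(acc), tolerance = 1e-12)
  expect_error(extract_tch(rg, list(xmin = 30, ymin = 0, xmax = 40,
                                    ymax = 5)), "no CHM cells")
})

test_that("height percentiles match an independent sort-and-interpolate oracle", {
  h <- seq(2.1, 12.0, by = 0.1)
  got <- height_percentiles(h, cutoff = 2)
  expect_equal(unname(got["h50"]), quantile_oracle(h, 0.5), tolerance = 1e-12)

  set.seed(15)
  for (i in 1:25) {
    v <- runif(sample(5:200, 1), 0, 30)
    got <- height_percentiles(v, cutoff = 0)
    for (p in c(25, 50, 75, 90, 95))
      expect_equal(unname(got[paste0("h", p)]),
                   quantile_oracle(v[v > 0], p / 100), tolerance = 1e-12)
    expect_true(!is.unsorted(got))
  }
  expect_equal(unname(height_percentiles(rep(7, 10))),
               rep(7, 5))
  expect_true(all(is.na(height_percentiles(c(0.5, 1.2), cutoff = 2))))
})

test_that("density metrics follow the relative-height exceedance definition", {
  set.seed(16)
  h <- runif(20000, 0, 18)
  d <- density_percentiles(h)
  expect_equal(unname(d), 1 - c(25, 50, 75, 90, 95) / 100, tolerance = 0.02)
  expect_true(all(diff(unname(d)) <= 0))
  expect_equal(unname(density_percentiles(rep(0, 5))), rep(0, 5))

  npc <- make_npc(runif(50), runif(50), runif(50, 3, 9))
  expect_equal(canopy_cover(npc, cc_threshold = 2), 1)
  npc2 <- rbind(npc, make_npc(0.1, 0.1, 0.5, class = "ground"))
  expect_equal(canopy_cover(npc2, cc_threshold = 2), 50 / 51)
})

test_that("plot metrics satisfy ordering invariants on simulated campaigns", {
  sim <- simulate_campaign(small_campaign(seed = 17))
  m <- sim$table
  hcols <- paste0("h", c(25, 50, 75, 90, 95))
  dcols <- paste0("d", c(25, 50, 75, 90, 95))
  for (i in seq_len(nrow(m))) {
    expect_true(!is.unsorted(as.numeric(m[i, hcols, with = FALSE])))
    expect_true(all(diff(as.numeric(m[i, dcols, with = FALSE])) <= 0))
  }
  expect_true(all(m$cc >= 0 & m$cc <= 1))
  # TCH cannot exceed the plot's maximum CHM value
  cells <- cell_centers(sim$chm)
  for (i in seq_len(nrow(sim$stand$plots))) {
    p <- sim$stand$plots[i]
    mx <- max(cells[x > p$xmin & x < p$xmax & y > p$ymin & y < p$ymax]$value)
    expect_lte(m$tch[i], mx + 1e-12)
  }
})

test_that("TCH underestimates a single cone apex", {
  for (h in c(8, 15, 22)) {
    st <- one_tree_stand(height = h, crown_base = 0.4 * h)
    cl <- classify_ground(simulate_point_cloud(
      st, lidar_sim_config(vertical_noise_sd = 0, noise_fraction = 0,
                           rng_seed = 18)))
    dem <- build_dem(cl, 2, c(0, 0, 20, 20), c(0, 0))
    npc <- normalize_heights(cl, dem)
    chm <- rasterize_chm(npc, 1, c(0, 0, 20, 20), c(0, 0))
    expect_lt(extract_tch(chm, st$plots[1]), h)
  }
})

test_that("CHM refinement stabilises as pixels shrink", {
  sim <- simulate_campaign(small_campaign(seed = 19))
  ext <- c(0, 0, max(sim$stand$plots$xmax), max(sim$stand$plots$ymax))
  chms <- lapply(c(1, 0.5, 0.25), function(px)
    rasterize_chm(sim$npc, px, ext, c(0, 0)))
  # evaluate every CHM at the finest-grid cell centres
  fine <- cell_centers(chms[[3]])
  val <- lapply(chms, function(g) {
    idx <- canopycarbon:::cell_index(g, fine$x, fine$y)
    g$values[cbind(idx$row, idx$col)]
  })
  expect_gte(mean(abs(val[[1]] - val[[2]])),
             mean(abs(val[[2]] - val[[3]])))
})

test_that("metrics join enforces plot-id agreement", {
  m <- data.table::data.table(plot_id = 1:3, tch = c(4, 5, 6))
  s <- data.table::data.table(plot_id = 2:4, acd = c(40, 50, 60))
  expect_error(plot_metrics_table(m, s), "1")
  expect_error(plot_metrics_table(m, s), "4")
  j <- plot_metrics_table(m[2:3], s[1:2])
  expect_equal(nrow(j), 2)
  expect_identical(j, plot_metrics_table(m[2:3], s[1:2]))
})
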