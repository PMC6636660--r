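test_that("stand generation follows the configured height curve exactly when noise-free", {
  cfg <- small_stand(seed = 3, height_curve = c(1.7, 0.55, 0),
                     top_damage = 0)
  st <- generate_stand(cfg)
  expect_equal(st$trees$height, 1.3 + 1.7 * st$trees$dbh^0.55,
               tolerance = 1e-12)
  expect_true(all(st$trees$dbh >= 5))
  expect_true(all(st$trees$height > 1.3))
  expect_true(all(st$trees$crown_base >= 0 &
                  st$trees$crown_base < st$trees$height))
  expect_true(all(st$trees$crown_radius > 0))
})

test_that("trees fall inside their plot squares", {
  st <- generate_stand(small_stand(seed = 11))
  tr <- merge(st$trees, st$plots, by = "plot_id")
  expect_true(all(tr$x >= tr$xmin & tr$x <= tr$xmax &
                  tr$y >= tr$ymin & tr$y <= tr$ymax))
})

test_that("stand and cloud generation are deterministic under a fixed seed", {
  cfg <- small_stand(seed = 99)
  st1 <- generate_stand(cfg); st2 <- generate_stand(cfg)
  expect_identical(st1$trees, st2$trees)
  lcfg <- lidar_sim_config(rng_seed = 42)
  expect_identical(simulate_point_cloud(st1, lcfg),
                   simulate_point_cloud(st2, lcfg))
})

test_that("default campaign matches the surveyed stem density", {
  # 94 plots with ~5734 trees in the reference campaign: ~61 stems/plot
  st <- generate_stand(stand_config(rng_seed = 5))
  expect_equal(nrow(st$plots), 94)
  mean_count <- nrow(st$trees) / 94
  expect_lt(abs(mean_count - 61) / 61, 0.10)
})

test_that("invalid stand configurations are rejected", {
  expect_error(stand_config(dbh_weibull = c(-1, 10)), "Weibull")
  # a scale putting too much mass below the 5 cm census threshold
  expect_error(stand_config(dbh_weibull = c(1.2, 10)), "census threshold")
  expect_error(stand_config(plot_side = 0))
  expect_error(lidar_sim_config(pulse_density = 0), "pulse_density")
  expect_error(lidar_sim_config(ground_penetration = 1.2))
})

test_that("treeless flat terrain yields only exact ground returns", {
  st <- treeless_stand(elev = 100)
  cl <- simulate_point_cloud(st, lidar_sim_config(vertical_noise_sd = 0,
                                                  noise_fraction = 0,
                                                  rng_seed = 1))
  expect_true(all(cl$class == "ground"))
  expect_equal(cl$z, rep(100, nrow(cl)), tolerance = 1e-12)
})

test_that("a single cone's apex height is recovered within pulse-spacing tolerance", {
  st <- one_tree_stand(height = 15, crown_base = 6, crown_radius = 1.6)
  cl <- simulate_point_cloud(st, lidar_sim_config(pulse_density = 50,
                                                  vertical_noise_sd = 0,
                                                  noise_fraction = 0,
                                                  rng_seed = 2))
  veg <- cl[cl$class == "vegetation", ]
  expect_gt(nrow(veg), 10)
  apex_z <- 100 + 15
  # no return can exceed the generating surface
  expect_true(all(veg$z <= apex_z + 1e-9))
  # nearest pulse to the apex axis is within ~sqrt(2) grid spacings;
  # cone slope (height-crown_base)/radius converts that to height deficit
  spacing <- 1 / sqrt(50)
  slope <- (15 - 6) / 1.6
  expect_lt(apex_z - max(veg$z), sqrt(2) * spacing * slope)
})

test_that("full penetration forces a ground echo under every canopy pulse", {
  st <- one_tree_stand()
  cl <- simulate_point_cloud(st, lidar_sim_config(ground_penetration = 1,
                                                  rng_seed = 3))
  veg <- cl[cl$class == "vegetation", ]
  expect_true(all(veg$n_returns >= 2))
})

test_that("realized pulse density matches the configuration", {
  st <- generate_stand(small_stand(seed = 21))
  cfg <- lidar_sim_config(ground_penetration = 0, noise_fraction = 0,
                          rng_seed = 4)
  cl <- simulate_point_cloud(st, cfg, buffer = 0)
  area <- diff(range(st$plots$xmax, st$plots$xmin)) *
          diff(range(st$plots$ymax, st$plots$ymin))
  # one return per pulse when penetration is off
  expect_lt(abs(nrow(cl) / area - cfg$pulse_density) / cfg$pulse_density,
            0.15)
})

test_that("vegetation returns stay below their stand's tallest apex", {
  st <- generate_stand(small_stand(seed = 31))
  cfg <- lidar_sim_config(rng_seed = 5)
  cl <- simulate_point_cloud(st, cfg)
  apex_max <- max(terrain_elevation(st$trees$x, st$trees$y,
                                    st$config$terrain) + st$trees$height)
  veg <- cl[cl$class == "vegetation", ]
  expect_true(all(veg$z <= apex_max + 3 * cfg$vertical_noise_sd))
})

test_that("point clouds round-trip through the plain-text format", {
  st <- generate_stand(small_stand(seed = 41, n_plots = 4L))
  cl <- simulate_point_cloud(st, lidar_sim_config(rng_seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_points(cl, path)
  back <- read_points(path)
  expect_identical(table(back$class), table(cl$class))
  expect_identical(back$return_number, cl$return_number)
  expect_identical(back$n_returns, cl$n_returns)
  expect_equal(back$x, cl$x, tolerance = 1e-3)
  expect_equal(back$z, cl$z, tolerance = 1e-3)
})

test_that("empty clouds and malformed files follow the i/o contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.table::data.table(x = numeric(), y = numeric(),
                                  z = numeric(), return_number = integer(),
                                  n_returns = integer(),
                                  class = character())
  write_points(empty, path)
  expect_equal(nrow(read_points(path)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x\ty\tz\treturn_number\tn_returns\tclass",
               "1\t2\t100.5\t1\t1\tground",
               "1\t2\toops\t1\t1\tground"), bad)
  expect_error(read_points(bad), "line 2")
})

test_that("LAS numeric classification codes are accepted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x\ty\tz\treturn_number\tn_returns\tclass",
               "0\t0\t100\t1\t2\t2",
               "0\t0\t110\t1\t1\t5",
               "0\t0\t300\t1\t1\t7"), path)
  cl <- read_points(path)
  expect_identical(cl$class, c("ground", "vegetation", "noise"))
})
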