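# Small-campaign configurations used across tests (fast but non-trivial).

small_stand <- function(seed = 1L, n_plots = 9L, ...) {
  stand_config(n_plots = n_plots, stems_per_plot = c(20L, 40L),
               rng_seed = seed, ...)
}

small_campaign <- function(seed = 1L, n_plots = 9L) {
  run_config(seed = seed,
             stand = stand_config(n_plots = n_plots,
                                  stems_per_plot = c(20L, 40L)),
             sensitivity_sizes = c(1, 2, 5))
}

# hand-built stand with a single conical tree on flat terrain
one_tree_stand <- function(height = 15, crown_base = 6, crown_radius = 1.6,
                           elev = 100) {
  cfg <- stand_config(n_plots = 1L, terrain = c(elev, 0), rng_seed = 1L)
  list(trees = data.table::data.table(
         plot_id = 1L, x = 10, y = 10, dbh = 20, height = height,
         crown_base = crown_base, crown_radius = crown_radius),
       plots = data.table::data.table(plot_id = 1L, xmin = 0, ymin = 0,
                                      xmax = 20, ymax = 20),
       config = cfg)
}

treeless_stand <- function(elev = 100) {
  st <- one_tree_stand(elev = elev)
  st$trees <- st$trees[0]
  st
}

# independent sort-and-interpolate quantile oracle (linear interpolation
# between order statistics, matching the documented rule)
quantile_oracle <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
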