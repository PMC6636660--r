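#' Carbon fraction of spruce aboveground biomass
#'
#' Multiplicative factor converting aboveground biomass (Mg ha^-1) to
#' aboveground carbon density (Mg C ha^-1), determined by potassium-dichromate
#' oxidation of Picea crassifolia samples in the study region.
#' @export
CARBON_FRACTION <- 0.5034

#' Per-tree biomass components for Qilian spruce
#'
#' Species-specific power-law allometry on the combined size variable
#' \eqn{D^2 H} (DBH in cm, height in m), returning component masses in kg:
#' \deqn{stem = 0.0478 (D^2 H)^{0.8665}}
#' \deqn{branch = 0.0061 (D^2 H)^{0.8905}}
#' \deqn{foliage = 0.2650 (D^2 H)^{0.4701}}
#' \deqn{fruit = 0.0342 (D^2 H)^{0.5779}}
#' Total aboveground biomass is the sum of the four components.
#'
#' @param dbh diameter at breast height, cm; must be >= 5 (inventory
#'   censuses only trees above this threshold).
#' @param height tree height, m; must exceed breast height (1.3 m).
#' @return data.frame with columns `stem`, `branch`, `foliage`, `fruit`,
#'   `total` (kg per tree), one row per input tree.
#' @examples
#' tree_biomass_components(20, 15)
#' @export
tree_biomass_components <- function(dbh, height) {
  if (length(dbh) != length(height))
    stop("dbh and height must have equal length")
  if (any(!is.finite(dbh)) || any(!is.finite(height)))
    stop("non-finite dbh or height")
  if (any(dbh < 5))
    stop("dbh below the 5 cm census threshold: ",
         paste(utils::head(which(dbh < 5), 5), collapse = ", "))
  if (any(height <= 1.3))
    stop("height must exceed breast height (1.3 m)")
  d2h <- dbh^2 * height
  stem    <- 0.0478 * d2h^0.8665
  branch  <- 0.0061 * d2h^0.8905
  foliage <- 0.2650 * d2h^0.4701
  fruit   <- 0.0342 * d2h^0.5779
  data.frame(stem = stem, branch = branch, foliage = foliage, fruit = fruit,
             total = stem + branch + foliage + fruit)
}

#' Plot aboveground biomass
#'
#' Sums per-tree total biomass (kg) over a plot and scales to Mg ha^-1 using
#' the exact plot area.
#'
#' @param trees data.frame with columns `dbh` (cm) and `height` (m).
#' @param plot_area plot area in m^2 (default 400 for a 20 m square plot).
#' @return AGB in Mg ha^-1.
#' @export
plot_agb <- function(trees, plot_area = 400) {
  stopifnot(plot_area > 0)
  if (nrow(trees) == 0) {
    warning("plot_agb: empty tree list, returning 0")
    return(0)
  }
  total_kg <- sum(tree_biomass_components(trees$dbh, trees$height)$total)
  # kg -> Mg (/1000), per-m2 -> per-ha (*1e4/area): net factor 10/area
  total_kg * 10 / plot_area
}

#' Convert aboveground biomass to carbon density
#'
#' @param agb aboveground biomass, Mg ha^-1 (>= 0).
#' @param carbon_fraction carbon content of dry biomass
#'   (default [CARBON_FRACTION]).
#' @return ACD in Mg C ha^-1.
#' @export
agb_to_acd <- function(agb, carbon_fraction = CARBON_FRACTION) {
  if (any(agb < 0)) stop("agb must be non-negative")
  agb * carbon_fraction
}

#' Plot-mean height metrics and basal area
#'
#' `avg_height` is the arithmetic mean tree height; `lorey_height` is the
#' basal-area-weighted mean height \eqn{\sum BA_i H_i / \sum BA_i};
#' `basal_area` is the summed stem cross-section at breast height
#' \eqn{\pi (D/200)^2} (D in cm) scaled to m^2 ha^-1.
#'
#' @param trees data.frame with columns `dbh` (cm) and `height` (m); at least
#'   one tree.
#' @param plot_area plot area, m^2.
#' @return a length-one numeric (m, or m^2 ha^-1 for `basal_area`).
#' @export
avg_height <- function(trees) {
  if (nrow(trees) == 0) stop("height metrics undefined for an empty plot")
  mean(trees$height)
}

#' @rdname avg_height
#' @export
lorey_height <- function(trees) {
  if (nrow(trees) == 0) stop("height metrics undefined for an empty plot")
  ba <- pi * (trees$dbh / 200)^2
  sum(ba * trees$height) / sum(ba)
}

#' @rdname avg_height
#' @export
basal_area <- function(trees, plot_area = 400) {
  stopifnot(plot_area > 0)
  if (nrow(trees) == 0) stop("basal area undefined for an empty plot")
  sum(pi * (trees$dbh / 200)^2) * 1e4 / plot_area
}

#' Summarise an inventory into per-plot response variables
#'
#' Computes, for every plot, tree count, AvgH, Lorey's height, basal area,
#' AGB and ACD. Trees below the 5 cm DBH census threshold are dropped first.
#'
#' @param trees data.frame/data.table with columns `plot_id`, `dbh`, `height`.
#' @param plot_area plot area in m^2, a single value or a named vector by
#'   plot id.
#' @param carbon_fraction see [agb_to_acd()].
#' @return data.table with one row per plot: `plot_id`, `n_trees`,
#'   `avg_height`, `lorey_height`, `basal_area`, `agb`, `acd`.
#' @export
plot_summaries <- function(trees, plot_area = 400,
                           carbon_fraction = CARBON_FRACTION) {
  dt <- data.table::as.data.table(trees)
  stopifnot(all(c("plot_id", "dbh", "height") %in% names(dt)))
  dt <- dt[dbh >= 5]
  if (nrow(dt) == 0) stop("no trees at or above the 5 cm DBH threshold")
  area_of <- function(id) {
    if (length(plot_area) == 1L && is.null(names(plot_area))) return(plot_area)
    a <- plot_area[[as.character(id)]]
    if (is.null(a)) stop("no plot area given for plot ", id)
    a
  }
  out <- dt[, {
    a <- area_of(.BY$plot_id)
    agb <- plot_agb(.SD, plot_area = a)
    list(n_trees = .N,
         avg_height = avg_height(.SD),
         lorey_height = lorey_height(.SD),
         basal_area = basal_area(.SD, plot_area = a),
         agb = agb,
         acd = agb_to_acd(agb, carbon_fraction))
  }, by = plot_id]
  data.table::setkey(out, plot_id)
  out[]
}

#' Read / write inventory tables
#'
#' Inventory CSV with columns `plot_id, tree_id, dbh_cm, height_m[, x, y]`;
#' read back as a data.table with internal names (`dbh`, `height`).
#'
#' @param trees tree table with columns `plot_id`, `dbh`, `height` and
#'   optionally `x`, `y`.
#' @param path file path.
#' @return `read_inventory` returns a data.table; `write_inventory` returns
#'   `path` invisibly.
#' @export
write_inventory <- function(trees, path) {
  dt <- data.table::as.data.table(trees)
  out <- data.table::data.table(plot_id = dt$plot_id,
                                tree_id = seq_len(nrow(dt)),
                                dbh_cm = dt$dbh, height_m = dt$height)
  if (all(c("x", "y") %in% names(dt))) out[, `:=`(x = dt$x, y = dt$y)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(path) {
  dt <- data.table::fread(path)
  need <- c("plot_id", "dbh_cm", "height_m")
  if (!all(need %in% names(dt)))
    stop("inventory file must have columns ", paste(need, collapse = ", "))
  data.table::setnames(dt, c("dbh_cm", "height_m"), c("dbh", "height"))
  dt[]
}
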