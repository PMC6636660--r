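#' Create a raster grid
#'
#' Lightweight in-memory raster used for DEM and CHM surfaces. Values are
#' stored as a matrix with row 1 at the southern edge, so cell `[r, c]` has
#' its centre at `origin + (c - 0.5, r - 0.5) * pixel_size`.
#'
#' @param origin numeric length-2, x/y of the lower-left corner (m).
#' @param pixel_size cell side (m), > 0.
#' @param n_rows,n_cols grid dimensions.
#' @param values numeric matrix `n_rows x n_cols`, or a single value to fill.
#' @param nodata marker for missing cells (default -9999).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(origin, pixel_size, n_rows, n_cols,
                        values = NA_real_, nodata = -9999) {
  stopifnot(length(origin) == 2, is.finite(origin), pixel_size > 0,
            n_rows >= 1, n_cols >= 1)
  if (is.matrix(values)) {
    stopifnot(nrow(values) == n_rows, ncol(values) == n_cols)
  } else {
    values <- matrix(values, nrow = n_rows, ncol = n_cols)
  }
  structure(
    list(origin = as.numeric(origin), pixel_size = pixel_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         values = values, nodata = nodata),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values) & x$values != x$nodata]
  cat(sprintf("raster_grid: %d x %d cells @ %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin[1], x$origin[2]))
  if (length(v)) {
    cat(sprintf("  values: min %.3f  mean %.3f  max %.3f  (%d filled)\n",
                min(v), mean(v), max(v), length(v)))
  }
  invisible(x)
}

#' Cell centre coordinates
#'
#' @param grid a `raster_grid`.
#' @return data.table with columns row, col, x, y, value.
#' @export
cell_centers <- function(grid) {
  idx <- data.table::CJ(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  idx[, `:=`(
    x = grid$origin[1] + (col - 0.5) * grid$pixel_size,
    y = grid$origin[2] + (row - 0.5) * grid$pixel_size,
    value = grid$values[cbind(row, col)])]
  idx[]
}

# row/col of the cell containing each (x, y); points on an upper edge are
# clamped into the last cell so a point exactly on the raster boundary counts.
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$pixel_size) + 1L
  row <- floor((y - grid$origin[2]) / grid$pixel_size) + 1L
  col <- pmin.int(pmax.int(col, 1L), grid$n_cols)
  row <- pmin.int(pmax.int(row, 1L), grid$n_rows)
  list(row = as.integer(row), col = as.integer(col))
}

is_filled <- function(grid) {
  !is.na(grid$values) & grid$values != grid$nodata
}

#' Fill empty raster cells by inverse-distance weighting
#'
#' Each empty (nodata) cell receives the IDW mean of the `k` nearest filled
#' cell centres, with weights `1/d^power`. Neighbours are located by an
#' expanding ring search on the grid, so cost scales with the number of empty
#' cells rather than the full grid.
#'
#' @param grid a `raster_grid`.
#' @param power IDW exponent (default 2).
#' @param k number of neighbours (default 12).
#' @return The grid with all cells filled (unchanged if none were empty).
#' @export
idw_fill <- function(grid, power = 2, k = 12) {
  filled <- is_filled(grid)
  if (all(filled)) return(grid)
  if (!any(filled)) stop("idw_fill: no filled cells to interpolate from")
  empty <- which(!filled, arr.ind = TRUE)
  vals <- grid$values
  out <- vals
  nr <- grid$n_rows; nc <- grid$n_cols
  for (i in seq_len(nrow(empty))) {
    r0 <- empty[i, 1L]; c0 <- empty[i, 2L]
    ring <- 1L
    repeat {
      rr <- max(1L, r0 - ring):min(nr, r0 + ring)
      cc <- max(1L, c0 - ring):min(nc, c0 + ring)
      sub <- filled[rr, cc, drop = FALSE]
      if (sum(sub) >= k || (length(rr) == nr && length(cc) == nc)) break
      ring <- ring + 1L
    }
    hit <- which(sub, arr.ind = TRUE)
    dr <- rr[hit[, 1L]] - r0
    dc <- cc[hit[, 2L]] - c0
    d2 <- (dr * dr + dc * dc) * grid$pixel_size^2
    v <- vals[cbind(rr[hit[, 1L]], cc[hit[, 2L]])]
    ord <- order(d2)[seq_len(min(k, length(d2)))]
    w <- 1 / sqrt(d2[ord])^power
    out[r0, c0] <- sum(w * v[ord]) / sum(w)
  }
  grid$values <- out
  grid
}

#' Bilinear interpolation of a raster at arbitrary points
#'
#' Interpolates between the four surrounding cell centres; coordinates beyond
#' the outermost centres are clamped to the edge (constant extrapolation).
#' A point exactly on a cell centre returns that cell's value.
#'
#' @param grid a fully filled `raster_grid`.
#' @param x,y point coordinates (m).
#' @return numeric vector of interpolated values.
#' @export
raster_bilinear <- function(grid, x, y) {
  px <- grid$pixel_size
  # fractional cell-centre coordinates
  gx <- (x - grid$origin[1]) / px - 0.5
  gy <- (y - grid$origin[2]) / px - 0.5
  gx <- pmin(pmax(gx, 0), grid$n_cols - 1L)
  gy <- pmin(pmax(gy, 0), grid$n_rows - 1L)
  c0 <- pmin.int(floor(gx) + 1L, grid$n_cols)
  r0 <- pmin.int(floor(gy) + 1L, grid$n_rows)
  c1 <- pmin.int(c0 + 1L, grid$n_cols)
  r1 <- pmin.int(r0 + 1L, grid$n_rows)
  fx <- gx - (c0 - 1L)
  fy <- gy - (r0 - 1L)
  v00 <- grid$values[cbind(r0, c0)]; v01 <- grid$values[cbind(r0, c1)]
  v10 <- grid$values[cbind(r1, c0)]; v11 <- grid$values[cbind(r1, c1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Read/write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values, northernmost
#' row first.
#'
#' @param grid a `raster_grid`.
#' @param path file path.
#' @return `read_ascii_grid` returns a `raster_grid`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  for (r in rev(seq_len(grid$n_rows))) {
    writeLines(paste(formatC(v[r, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    if (!length(ln)) stop("read_ascii_grid: missing header field ", key)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(getv("ncols")); nr <- as.integer(getv("nrows"))
  vals <- matrix(NA_real_, nrow = nr, ncol = nc)
  body <- lines[-(1:6)]
  if (length(body) != nr) stop("read_ascii_grid: expected ", nr, " data rows")
  for (i in seq_len(nr)) {
    row <- as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]])
    if (length(row) != nc) stop("read_ascii_grid: row ", i, " has ",
                                length(row), " values, expected ", nc)
    vals[nr - i + 1L, ] <- row
  }
  nd <- getv("NODATA_value")
  vals[vals == nd] <- NA_real_
  raster_grid(origin = c(getv("xllcorner"), getv("yllcorner")),
              pixel_size = getv("cellsize"), n_rows = nr, n_cols = nc,
              values = vals, nodata = nd)
}
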