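#' Regular grid specification
#'
#' Defines a planar regular grid (projected coordinates, metres). Cell
#' `[row, col]` covers `x` in `[xmin + (col-1)*cell, xmin + col*cell)` and
#' analogously in `y`; matrices indexed `[row, col]` with row 1 at `ymin`.
#'
#' @param ncols,nrows grid dimensions (>= 4 each for field synthesis).
#' @param cell cell size in metres.
#' @param xmin,ymin origin of the lower-left cell edge, metres.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(ncols, nrows, cell, xmin = 0, ymin = 0) {
  stopifnot(ncols >= 1, nrows >= 1, cell > 0)
  structure(list(ncols = as.integer(ncols), nrows = as.integer(nrows),
                 cell = cell, xmin = xmin, ymin = ymin,
                 xmax = xmin + ncols * cell, ymax = ymin + nrows * cell),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, extent [%g, %g] x [%g, %g]\n",
              x$nrows, x$ncols, x$cell, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

# row/col of the cell containing (x, y); NA outside the extent
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cell) + 1L
  row <- floor((y - grid$ymin) / grid$cell) + 1L
  bad <- col < 1L | col > grid$ncols | row < 1L | row > grid$nrows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col)
}

# value of matrix `m` at the cell containing each (x, y) (point-in-cell lookup)
cell_value <- function(grid, m, x, y) {
  ix <- cell_index(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(ix$row)
  out[ok] <- m[cbind(ix$row[ok], ix$col[ok])]
  out
}

# coordinates of all cell centers, column-major over [row, col]
cell_centers <- function(grid) {
  xs <- grid$xmin + (seq_len(grid$ncols) - 0.5) * grid$cell
  ys <- grid$ymin + (seq_len(grid$nrows) - 0.5) * grid$cell
  list(x = rep(xs, each = grid$nrows), y = rep(ys, times = grid$ncols))
}

#' Write a grid layer to CSV
#'
#' Long-format export (`x`, `y`, `value`) of one grid layer, the package's
#' plain-text raster interchange format.
#'
#' @param grid a [grid_spec()].
#' @param m matrix of values (`nrows` x `ncols`).
#' @param path output CSV path.
#' @export
write_grid_csv <- function(grid, m, path) {
  cc <- cell_centers(grid)
  utils::write.csv(data.frame(x = cc$x, y = cc$y, value = as.vector(m)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Project longitude/latitude to planar metres
#'
#' Spherical Lambert azimuthal equal-area projection centred on (10E, 52N),
#' the same centre as the ETRS89-LAEA grid commonly used for pan-European
#' layers. Adequate for ingesting lon/lat records onto the package's planar
#' grids; not a datum-exact EPSG:3035 transform.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param lon0,lat0 projection centre, degrees.
#' @return list with planar `x`, `y` in metres.
#' @export
project_lonlat <- function(lon, lat, lon0 = 10, lat0 = 52) {
  R <- 6371000
  to_rad <- pi / 180
  l <- lon * to_rad; p <- lat * to_rad
  l0 <- lon0 * to_rad; p0 <- lat0 * to_rad
  k <- sqrt(2 / (1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)))
  list(x = R * k * cos(p) * sin(l - l0),
       y = R * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0)))
}
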