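#' Regular analysis grid over a rectangular observation window
#'
#' The observation window is a rectangle in planar km coordinates, tiled
#' by square cells (default 1 km^2, the resolution used for the risk
#' maps). Cells are indexed k = 1..K in row-major order (x fastest).
#'
#' @param width_km,height_km window extent in km.
#' @param cell_km cell side length in km (default 1).
#' @param origin lower-left corner, c(x, y) in km (default c(0, 0)).
#' @return an object of class \code{grid_spec}: list with \code{window}
#'   (2-column matrix of rectangle vertices, closed ring), \code{cells}
#'   (data.frame k, x, y of centroids), \code{nx}, \code{ny},
#'   \code{cell_km}, \code{origin}.
#' @export
make_grid <- function(width_km, height_km, cell_km = 1, origin = c(0, 0)) {
  stopifnot(width_km > 0, height_km > 0, cell_km > 0)
  nx <- as.integer(round(width_km / cell_km))
  ny <- as.integer(round(height_km / cell_km))
  if (nx < 1L || ny < 1L) stop("window smaller than one cell", call. = FALSE)
  cx <- origin[1] + (seq_len(nx) - 0.5) * cell_km
  cy <- origin[2] + (seq_len(ny) - 0.5) * cell_km
  cells <- data.frame(k = seq_len(nx * ny),
                      x = rep(cx, times = ny),
                      y = rep(cy, each = nx))
  win <- cbind(x = origin[1] + c(0, nx, nx, 0, 0) * cell_km,
               y = origin[2] + c(0, 0, ny, ny, 0) * cell_km)
  structure(list(window = win, cells = cells, nx = nx, ny = ny,
                 cell_km = cell_km, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.3g km (%d cells)\n",
              x$nx, x$ny, x$cell_km, nrow(x$cells)))
  invisible(x)
}

# map point coordinates to cell indices (row-major, x fastest);
# points on the upper/right boundary are assigned to the last cell
cell_index <- function(grid, x, y) {
  ix <- pmin(pmax(floor((x - grid$origin[1]) / grid$cell_km), 0), grid$nx - 1)
  iy <- pmin(pmax(floor((y - grid$origin[2]) / grid$cell_km), 0), grid$ny - 1)
  as.integer(iy * grid$nx + ix + 1)
}
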