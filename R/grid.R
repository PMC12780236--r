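#' Define a projected equal-area analysis grid
#'
#' All rasters in the pipeline live on a shared north-up grid in a projected
#' equal-area CRS with coordinates in metres. Pixel `(i, j)` (1-based, row 1
#' at the top) covers the half-open square
#' `[origin_x + (j-1)*res, origin_x + j*res)` in x and
#' `(origin_y - i*res, origin_y - (i-1)*res]` in y, so `origin_x, origin_y`
#' is the top-left corner of the extent.
#'
#' @param origin_x,origin_y Top-left corner of the grid, metres.
#' @param n_rows,n_cols Grid dimensions, each at least 1.
#' @param resolution Pixel edge length in metres (default 500, the native
#'   analysis resolution).
#' @param crs_id Free-text CRS token; all layers in one run must share it.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x = 0, origin_y = NULL, n_rows = 100L,
                      n_cols = 100L, resolution = 500, crs_id = "synthetic-equal-area-m") {
  stopifnot(resolution > 0, n_rows >= 1, n_cols >= 1)
  if (is.null(origin_y)) origin_y <- n_rows * resolution
  structure(
    list(origin_x = origin_x, origin_y = origin_y,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         resolution = resolution, crs_id = crs_id),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g m (%s)\n",
              x$n_rows, x$n_cols, x$resolution, x$crs_id))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A `grid_spec`.
#' @return Integer cell count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Area of one pixel in square kilometres
#' @param grid A `grid_spec`.
#' @return Pixel area in km^2 (0.25 at 500 m).
#' @export
cell_area_km2 <- function(grid) (grid$resolution / 1000)^2

grid_extent <- function(grid) {
  c(xmin = grid$origin_x,
    xmax = grid$origin_x + grid$n_cols * grid$resolution,
    ymin = grid$origin_y - grid$n_rows * grid$resolution,
    ymax = grid$origin_y)
}

#' Map point coordinates to grid cells
#'
#' Uses the half-open pixel rule: a point on a vertical cell edge belongs to
#' the pixel to its right, a point on a horizontal edge to the pixel below
#' the edge (the top edge of the extent belongs to row 1).
#'
#' @param grid A `grid_spec`.
#' @param x,y Numeric coordinate vectors (metres, grid CRS).
#' @return Integer vector of cell indices (column-major, as in an R matrix);
#'   `NA` for points outside the extent.
#' @export
cell_from_xy <- function(grid, x, y) {
  ext <- grid_extent(grid)
  j <- floor((x - grid$origin_x) / grid$resolution) + 1
  i <- floor((grid$origin_y - y) / grid$resolution) + 1
  # top edge of the extent folds into row 1
  i[y == ext["ymax"]] <- 1
  ok <- x >= ext["xmin"] & x < ext["xmax"] & y > ext["ymin"] & y <= ext["ymax"]
  idx <- ifelse(ok, (j - 1) * grid$n_rows + i, NA_integer_)
  as.integer(idx)
}

#' Cell-centre coordinates of grid cells
#' @param grid A `grid_spec`.
#' @param cells Integer cell indices (column-major).
#' @return A two-column matrix of x, y centre coordinates.
#' @export
xy_from_cell <- function(grid, cells) {
  i <- ((cells - 1) %% grid$n_rows) + 1
  j <- ((cells - 1) %/% grid$n_rows) + 1
  cbind(x = grid$origin_x + (j - 0.5) * grid$resolution,
        y = grid$origin_y - (i - 0.5) * grid$resolution)
}

#' Test whether points fall inside the grid extent
#' @inheritParams cell_from_xy
#' @return Logical vector.
#' @export
in_grid <- function(grid, x, y) !is.na(cell_from_xy(grid, x, y))

#' Cell indices whose centres lie within a radius of a point
#'
#' @param grid A `grid_spec`.
#' @param x,y Disc centre (metres).
#' @param radius_m Disc radius in metres.
#' @return Integer vector of cell indices (possibly empty after clipping to
#'   the grid).
#' @export
cells_in_disc <- function(grid, x, y, radius_m) {
  res <- grid$resolution
  jmin <- max(1L, floor((x - radius_m - grid$origin_x) / res) + 1L)
  jmax <- min(grid$n_cols, floor((x + radius_m - grid$origin_x) / res) + 1L)
  imin <- max(1L, floor((grid$origin_y - (y + radius_m)) / res) + 1L)
  imax <- min(grid$n_rows, floor((grid$origin_y - (y - radius_m)) / res) + 1L)
  if (jmin > jmax || imin > imax) return(integer(0))
  jj <- jmin:jmax
  ii <- imin:imax
  cx <- grid$origin_x + (jj - 0.5) * res
  cy <- grid$origin_y - (ii - 0.5) * res
  d2 <- outer(cy - y, cx - x, function(a, b) a^2 + b^2)
  keep <- which(d2 <= radius_m^2)
  i <- ((keep - 1) %% length(ii)) + imin
  j <- ((keep - 1) %/% length(ii)) + jmin
  as.integer((j - 1) * grid$n_rows + i)
}

stop_if_grid_mismatch <- function(a, b) {
  if (a$n_rows != b$n_rows || a$n_cols != b$n_cols ||
      a$resolution != b$resolution || a$origin_x != b$origin_x ||
      a$origin_y != b$origin_y) {
    stop("grids are not co-registered", call. = FALSE)
  }
  if (!identical(a$crs_id, b$crs_id)) {
    stop("CRS mismatch between layers: '", a$crs_id, "' vs '", b$crs_id, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}
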