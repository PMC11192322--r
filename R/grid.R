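#' Regular prediction grid
#'
#' Square cells; predictions are made at cell centres, i.e. at
#' origin + (i + 0.5) * cell_size for i = 0, ..., n - 1 along each axis.
#'
#' @param origin numeric length 2, lower-left corner (x0, y0).
#' @param cell_size side length of a (square) cell, > 0.
#' @param nx,ny number of cells along x and y.
#' @param mask optional logical vector (length nx*ny, TRUE = keep cell).
#' @return Object of class `prediction_grid`.
#' @export
prediction_grid <- function(origin = c(0, 0), cell_size, nx, ny, mask = NULL) {
  stopifnot(length(origin) == 2, cell_size > 0, nx >= 1, ny >= 1)
  if (!is.null(mask) && length(mask) != nx * ny)
    stop("mask must have one entry per cell")
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 nx = as.integer(nx), ny = as.integer(ny), mask = mask),
            class = "prediction_grid")
}

#' Unit-square grid helper
#' @param res cells per side.
#' @export
unit_square_grid <- function(res = 25) prediction_grid(c(0, 0), 1 / res, res, res)

#' Cell-centre coordinates of a prediction grid
#' @param grid a [prediction_grid()].
#' @return A point set (data frame x, y), row-major in x then y.
#' @export
grid_centres <- function(grid) {
  stopifnot(inherits(grid, "prediction_grid"))
  cx <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$cell_size
  cy <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$cell_size
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  points_df(g$x, g$y)
}

#' Per-cell mean/sd surface on a prediction grid
#'
#' @param grid a [prediction_grid()].
#' @param mean,sd numeric vectors, one entry per cell (NA for masked cells).
#' @param quantity name of the mapped quantity (e.g. "log_odds",
#'   "probability", or a covariate name).
#' @return Object of class `grid_map`.
#' @export
grid_map <- function(grid, mean, sd, quantity = "value") {
  stopifnot(inherits(grid, "prediction_grid"))
  ncell <- grid$nx * grid$ny
  if (length(mean) != ncell || length(sd) != ncell)
    stop("mean and sd must have one entry per grid cell")
  if (any(sd < 0, na.rm = TRUE)) stop("sd must be non-negative")
  structure(list(grid = grid, mean = as.numeric(mean), sd = as.numeric(sd),
                 quantity = quantity),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("grid_map of %s: %d x %d cells, mean range [%.3g, %.3g]\n",
              x$quantity, x$grid$nx, x$grid$ny,
              min(x$mean, na.rm = TRUE), max(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.grid_map <- function(x, ...) {
  ctr <- grid_centres(x$grid)
  data.frame(cell_x = ctr$x, cell_y = ctr$y, mean = x$mean, sd = x$sd)
}
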