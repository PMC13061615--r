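#' Define a planar analysis grid
#'
#' The analysis raster: a rectangular grid of square cells in planar metric
#' coordinates (eastings/northings). Cell `(col, row)` (0-based) covers the
#' half-open square `[origin + col * cell_size, origin + (col + 1) * cell_size)`
#' and likewise for northings, so every point in the window belongs to exactly
#' one cell. The default mirrors a 26 km x 26 km urban window at 1 km
#' resolution, the coarsest residential geocoding commonly released by large
#' cohort studies.
#'
#' @param origin_easting,origin_northing Coordinates of the grid's south-west
#'   corner, in metres.
#' @param cell_size Side length of a cell, in metres. Default 1000.
#' @param n_cols,n_rows Number of columns (eastings) and rows (northings).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(n_cols = 26, n_rows = 26)
#' @export
grid_spec <- function(origin_easting = 0, origin_northing = 0,
                      cell_size = 1000, n_cols = 26, n_rows = 26) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("`cell_size` must be a single positive number.")
  }
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || n_cols < 2 || is.na(n_rows) || n_rows < 2) {
    abort("`n_cols` and `n_rows` must both be >= 2.")
  }
  structure(
    list(
      origin_easting = as.numeric(origin_easting),
      origin_northing = as.numeric(origin_northing),
      cell_size = as.numeric(cell_size),
      n_cols = n_cols,
      n_rows = n_rows
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g m, origin (%g, %g), extent %g x %g km\n",
    x$n_cols, x$n_rows, x$cell_size, x$origin_easting, x$origin_northing,
    x$n_cols * x$cell_size / 1000, x$n_rows * x$cell_size / 1000
  ))
  invisible(x)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

# 1-based linear cell id from 0-based (col, row); row-major, row 0 first
cell_id <- function(col, row, grid) row * grid$n_cols + col + 1L

#' Cell centres of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: `cell` (1-based linear id,
#'   row-major from the south-west corner), 0-based `col` and `row`, and the
#'   `easting`/`northing` of the cell centre in metres.
#' @export
cell_centres <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  row <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  tibble(
    cell = seq_len(n_cells(grid)),
    col = col,
    row = row,
    easting = grid$origin_easting + (col + 0.5) * grid$cell_size,
    northing = grid$origin_northing + (row + 0.5) * grid$cell_size
  )
}

#' Snap point coordinates to grid cells
#'
#' Maps planar coordinates to the 0-based `(col, row)` index of the cell that
#' contains them, under the half-open cell convention: a point exactly on a
#' shared cell boundary belongs to the cell on its east/north side, and a
#' point exactly on the grid's east or north edge is out of bounds.
#'
#' @param easting,northing Numeric vectors of coordinates in metres.
#' @param grid A [grid_spec()].
#' @return A tibble with columns `col`, `row` (0-based) and `cell` (1-based
#'   linear id).
#' @examples
#' g <- grid_spec(origin_easting = 400000, origin_northing = 280000)
#' snap_to_grid(412500, 291500, g)
#' @export
snap_to_grid <- function(easting, northing, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(easting) != length(northing)) {
    abort("`easting` and `northing` must have the same length.")
  }
  col <- floor((easting - grid$origin_easting) / grid$cell_size)
  row <- floor((northing - grid$origin_northing) / grid$cell_size)
  bad <- which(!is.finite(col) | !is.finite(row) |
                 col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows)
  if (length(bad) > 0) {
    k <- bad[1]
    abort(sprintf(
      "%d point(s) outside the grid; first offender: (%g, %g).",
      length(bad), easting[k], northing[k]
    ))
  }
  col <- as.integer(col)
  row <- as.integer(row)
  tibble(col = col, row = row, cell = cell_id(col, row, grid))
}

# internal: home cell ids for a cohort table
home_cells <- function(data, grid) {
  snap_to_grid(data$easting, data$northing, grid)$cell
}

#' Present a per-cell map as a tibble
#'
#' @param values Numeric (or logical) vector with one entry per grid cell, in
#'   linear cell order.
#' @param grid A [grid_spec()].
#' @param name Column name for the values. Default `"value"`.
#' @return A tibble: `cell`, `col`, `row`, `easting`, `northing`, and the
#'   value column.
#' @export
map_tibble <- function(values, grid, name = "value") {
  stopifnot(inherits(grid, "grid_spec"), length(values) == n_cells(grid))
  out <- cell_centres(grid)
  out[[name]] <- as.vector(values)
  out
}

# internal: per-cell vector -> n_rows x n_cols matrix (row index = grid row)
map_matrix <- function(values, grid) {
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

# internal: intersection of two grids' windows, as cell ids in each
grid_intersection <- function(grid_a, grid_b) {
  ca <- cell_centres(grid_a)
  inside_b <- ca$easting > grid_b$origin_easting &
    ca$easting < grid_b$origin_easting + grid_b$n_cols * grid_b$cell_size &
    ca$northing > grid_b$origin_northing &
    ca$northing < grid_b$origin_northing + grid_b$n_rows * grid_b$cell_size
  cells_a <- ca$cell[inside_b]
  if (length(cells_a) == 0) {
    return(list(cells_a = integer(0), cells_b = integer(0)))
  }
  sb <- snap_to_grid(ca$easting[inside_b], ca$northing[inside_b], grid_b)
  list(cells_a = cells_a, cells_b = sb$cell)
}
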