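#' Define the cell grid of a model area
#'
#' Each model area is a rectangular sheet of excitatory cells (with a matched
#' sheet of inhibitory cells of the same dimensions). Cells are indexed
#' column-major, i.e. cell id `(col - 1) * rows + row`.
#'
#' @param rows,cols Positive integer grid dimensions. The default 25 x 25
#'   gives 625 excitatory cells per area.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(25, 25)
#' n_cells(g)
#' @export
grid_spec <- function(rows = 25L, cols = 25L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(length(rows) == 1L, length(cols) == 1L, rows >= 1L, cols >= 1L)
  structure(list(rows = rows, cols = cols), class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$rows * grid$cols
}

#' Grid coordinates of cell ids
#'
#' @param grid A `grid_spec`.
#' @param cells Integer cell ids in `1:n_cells(grid)`; default all cells.
#' @return A tibble with columns `cell`, `row`, `col`.
#' @export
grid_coords <- function(grid, cells = seq_len(n_cells(grid))) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- as.integer(cells)
  tibble::tibble(
    cell = cells,
    row = ((cells - 1L) %% grid$rows) + 1L,
    col = ((cells - 1L) %/% grid$rows) + 1L
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d (%d cells)\n", x$rows, x$cols, x$rows * x$cols))
  invisible(x)
}

# Chebyshev (chessboard) distance between two grid positions, with optional
# toroidal wrap-around.
chebyshev_dist <- function(r1, c1, r2, c2, grid, torus = FALSE) {
  dr <- abs(r1 - r2); dc <- abs(c1 - c2)
  if (torus) {
    dr <- pmin(dr, grid$rows - dr)
    dc <- pmin(dc, grid$cols - dc)
  }
  pmax(dr, dc)
}
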