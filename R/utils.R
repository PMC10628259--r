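# Grid conventions used throughout:
#  - a raster is a numeric vector of length nrow*ncol in column-major order
#    (cell id = row + (col-1)*nrow), or equivalently a matrix[nrow, ncol];
#  - row 1 is the "southern" edge, increasing rows point poleward ("north");
#  - cell (r, c) has its center at x = c - 0.5, y = r - 0.5 in grid units;
#  - cell membership uses half-open intervals [x0, x0 + 1) per axis.

#' Define a planning grid
#'
#' A minimal grid definition in projected units: origin, cell size, and
#' dimensions. Used to bin point records into cells and to interpret raster
#' vectors.
#'
#' @param nrow,ncol Positive integer grid dimensions.
#' @param cell_size Side length of a (square) cell in map units. Default 1.
#' @param xmin,ymin Coordinates of the grid's lower-left (south-west) corner.
#' @return An object of class `grid_def`.
#' @export
grid_def <- function(nrow, ncol, cell_size = 1, xmin = 0, ymin = 0) {
  if (length(nrow) != 1 || length(ncol) != 1 || nrow < 1 || ncol < 1 ||
      nrow != as.integer(nrow) || ncol != as.integer(ncol)) {
    abort("`nrow` and `ncol` must be positive integers.")
  }
  if (cell_size <= 0) abort("`cell_size` must be positive.")
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         cell_size = cell_size, xmin = xmin, ymin = ymin),
    class = "grid_def"
  )
}

#' @export
print.grid_def <- function(x, ...) {
  cat(sprintf("<grid_def> %d x %d cells, cell size %g, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell_size, x$xmin, x$ymin))
  invisible(x)
}

n_cells <- function(grid) grid$nrow * grid$ncol

cell_index <- function(row, col, nrow) as.integer(row + (col - 1L) * nrow)

cell_row <- function(cell, nrow) as.integer((cell - 1L) %% nrow + 1L)
cell_col <- function(cell, nrow) as.integer((cell - 1L) %/% nrow + 1L)

# half-open binning of points into cells; returns NA for out-of-grid points
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cell_size) + 1
  row <- floor((y - grid$ymin) / grid$cell_size) + 1
  ok <- row >= 1 & row <= grid$nrow & col >= 1 & col <= grid$ncol
  out <- rep(NA_integer_, length(x))
  out[ok] <- cell_index(row[ok], col[ok], grid$nrow)
  out
}

cell_center_xy <- function(grid, cell) {
  list(x = grid$xmin + (cell_col(cell, grid$nrow) - 0.5) * grid$cell_size,
       y = grid$ymin + (cell_row(cell, grid$nrow) - 0.5) * grid$cell_size)
}

# "southness": 1 at row 1, 0 at row nrow
southness <- function(row, nrow) {
  if (nrow == 1) return(rep(0, length(row)))
  1 - (row - 1) / (nrow - 1)
}

#' Convert a raster vector to a tidy tibble
#'
#' @param x Numeric vector of length `nrow * ncol` (column-major) or a matrix.
#' @param nrow,ncol Grid dimensions; taken from `dim(x)` when `x` is a matrix.
#' @return A tibble with columns `cell`, `row`, `col`, `value`.
#' @export
raster_tbl <- function(x, nrow = NULL, ncol = NULL) {
  if (is.matrix(x)) {
    nrow <- base::nrow(x); ncol <- base::ncol(x); x <- as.vector(x)
  }
  stopifnot(length(x) == nrow * ncol)
  cell <- seq_along(x)
  tibble::tibble(cell = cell, row = cell_row(cell, nrow),
                 col = cell_col(cell, nrow), value = x)
}

check_same_length <- function(..., what = "rasters") {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1) {
    abort(sprintf("misaligned %s: lengths %s", what, paste(lens, collapse = ", ")))
  }
  invisible(lens[1])
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
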