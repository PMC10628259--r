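# Occurrence-record cleaning operators: grid-and-thin, k-nearest-neighbour
# mean-distance outlier removal, and buffered range truncation. These are the
# generic cleaning steps applied to aggregated point archives before species
# distributions enter a planning workflow.

#' Grid and thin occurrence points
#'
#' Bins point records into grid cells (half-open cell intervals, so a point
#' exactly on a boundary belongs to the cell on its north/east side) and keeps
#' at most one record per species per cell. Points falling outside the grid
#' are dropped with a message.
#'
#' @param points A data frame with columns `x`, `y`, `species_id`.
#' @param grid A [grid_def()].
#' @return A tibble with one row per occupied species-cell: `species_id`,
#'   `cell`, `row`, `col`.
#' @export
#' @examples
#' g <- grid_def(10, 10)
#' pts <- tibble::tibble(x = c(0.2, 0.3, 5.5), y = c(0.2, 0.4, 2.5),
#'                       species_id = c("a", "a", "a"))
#' grid_and_thin(pts, g) # two occupied cells: the first two points collapse
grid_and_thin <- function(points, grid) {
  stopifnot(inherits(grid, "grid_def"))
  if (nrow(points) == 0) {
    warn("empty occurrence set: returning zero presence cells")
    return(tibble::tibble(species_id = character(), cell = integer(),
                          row = integer(), col = integer()))
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    abort("non-finite coordinates in occurrence set")
  }
  cell <- xy_to_cell(grid, points$x, points$y)
  n_out <- sum(is.na(cell))
  if (n_out > 0) {
    inform(sprintf("dropped %d point(s) outside the grid", n_out))
  }
  tibble::tibble(species_id = points$species_id, cell = cell) |>
    dplyr::filter(!is.na(.data$cell)) |>
    dplyr::distinct(.data$species_id, .data$cell) |>
    dplyr::mutate(row = cell_row(.data$cell, grid$nrow),
                  col = cell_col(.data$cell, grid$nrow)) |>
    dplyr::arrange(.data$species_id, .data$cell)
}

#' Remove spatial outliers by mean distance to k nearest neighbours
#'
#' For each species independently, computes every point's mean Euclidean
#' distance to its `k` nearest *other* points and removes points whose mean
#' exceeds a threshold. A single pass is made (no iteration), and species with
#' `k` or fewer points pass through unchanged because the statistic is
#' undefined for them. Using the mean of several neighbours (rather than the
#' single nearest) catches erroneous records that were logged more than once
#' at nearly the same spot.
#'
#' @param points A data frame with columns `x`, `y`, `species_id`.
#' @param max_mean_dist Positive distance threshold in map units; either a
#'   single value for all species or a named vector keyed by group (requires
#'   `groups`).
#' @param k Number of nearest neighbours (default 3).
#' @param groups Optional data frame `species_id`, `group` mapping species to
#'   the group whose threshold applies.
#' @return The filtered points tibble (a subset of the input rows), with
#'   per-species removal counts reported via a message.
#' @export
knn_outlier_filter <- function(points, max_mean_dist, k = 3, groups = NULL) {
  if (any(max_mean_dist <= 0)) abort("`max_mean_dist` must be positive")
  if (k < 1) abort("`k` must be >= 1")
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) return(points)

  thr_for <- function(sp) {
    if (length(max_mean_dist) == 1 && is.null(names(max_mean_dist))) {
      return(unname(max_mean_dist))
    }
    if (is.null(groups)) {
      abort("named `max_mean_dist` requires a `groups` table")
    }
    g <- groups$group[match(sp, groups$species_id)]
    if (is.na(g) || !g %in% names(max_mean_dist)) {
      abort(sprintf("no outlier threshold for species '%s'", sp))
    }
    unname(max_mean_dist[[g]])
  }

  keep <- rep(TRUE, nrow(points))
  removed <- integer(0)
  for (sp in unique(points$species_id)) {
    idx <- which(points$species_id == sp)
    if (length(idx) <= k) next
    d <- as.matrix(dist(cbind(points$x[idx], points$y[idx])))
    diag(d) <- Inf
    mean_knn <- apply(d, 1, function(row) mean(sort(row)[seq_len(k)]))
    bad <- mean_knn > thr_for(sp)
    keep[idx[bad]] <- FALSE
    if (any(bad)) removed[sp] <- sum(bad)
  }
  if (length(removed) > 0) {
    inform(paste0("knn_outlier_filter removed ",
                  paste(sprintf("%s: %d", names(removed), removed),
                        collapse = ", ")))
  }
  points[keep, , drop = FALSE]
}

# ray-casting point-in-polygon; polygon = matrix with columns x, y (open ring)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# min distance from points to polygon boundary segments
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    dmin <- pmin(dmin, d)
    j <- i
  }
  dmin
}

#' Truncate a suitability surface to a buffered range polygon
#'
#' Sets suitability to zero in every cell whose center lies outside the range
#' polygon dilated by `buffer` map units, leaving cells inside untouched. This
#' is the guard against model projections placing species implausibly far
#' from their documented range (e.g. capping projections at 500 km beyond a
#' published range polygon on a 1-km grid).
#'
#' @param suitability Raster vector (length `nrow*ncol`) or matrix.
#' @param polygon Two-column matrix of polygon vertices (x, y), open ring.
#' @param buffer Nonnegative dilation distance in map units.
#' @param grid A [grid_def()] giving the raster's geometry.
#' @return The truncated raster in the same shape as the input.
#' @export
buffer_range_truncate <- function(suitability, polygon, buffer, grid) {
  if (buffer < 0) abort("`buffer` must be nonnegative")
  was_matrix <- is.matrix(suitability)
  v <- as.vector(suitability)
  stopifnot(length(v) == n_cells(grid))
  if (is.null(polygon) || nrow(polygon) < 3) {
    warn("empty or degenerate polygon: returning all-zero raster")
    out <- v * 0
  } else {
    ctr <- cell_center_xy(grid, seq_along(v))
    keep <- point_in_polygon(ctr$x, ctr$y, polygon)
    if (buffer > 0) {
      idx_out <- which(!keep)
      near <- dist_to_polygon(ctr$x[idx_out], ctr$y[idx_out], polygon) <= buffer
      keep[idx_out[near]] <- TRUE
    }
    out <- v
    out[!keep] <- 0
  }
  if (was_matrix) matrix(out, grid$nrow, grid$ncol) else out
}
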