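# Plain-text I/O: ESRI-ASCII-style grids for rasters, CSV for tables and
# point sets, Newick for trees. All formats round-trip exactly enough for
# analysis (full double precision in the grid writer).

#' Write a raster to an ASCII grid file
#'
#' ESRI-ASCII-style text raster: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from the northern row downwards. `NA` is written as the nodata
#' value.
#'
#' @param x Raster vector (column-major) or matrix.
#' @param path Output file path.
#' @param grid A [grid_def()]; inferred from `dim(x)` for a matrix with
#'   default origin and cell size.
#' @param nodata Nodata sentinel. Default -9999.
#' @export
write_raster_ascii <- function(x, path, grid = NULL, nodata = -9999) {
  if (is.matrix(x) && is.null(grid)) grid <- grid_def(nrow(x), ncol(x))
  stopifnot(!is.null(grid))
  m <- matrix(as.vector(x), grid$nrow, grid$ncol)
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$ncol), sprintf("nrows %d", grid$nrow),
           sprintf("xllcorner %.10g", grid$xmin),
           sprintf("yllcorner %.10g", grid$ymin),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  rows <- vapply(rev(seq_len(grid$nrow)), function(r) {
    paste(format(m[r, ], digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ASCII grid file written by [write_raster_ascii()]
#'
#' @param path File path.
#' @return A list with `values` (column-major raster vector, nodata as `NA`)
#'   and `grid` (a [grid_def()]).
#' @export
read_raster_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " +")
  vals <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                   tolower(vapply(hdr, `[`, "", 1)))
  g <- grid_def(vals[["nrows"]], vals[["ncols"]], vals[["cellsize"]],
                vals[["xllcorner"]], vals[["yllcorner"]])
  m <- matrix(0, g$nrow, g$ncol)
  body <- lines[-(1:6)]
  for (i in seq_along(body)) {
    m[g$nrow - i + 1, ] <- as.numeric(strsplit(trimws(body[i]), " +")[[1]])
  }
  m[m == vals[["nodata_value"]]] <- NA
  list(values = as.vector(m), grid = g)
}

#' Write a suitability stack as a sparse long-format CSV
#'
#' Columns `cell`, `species_id`, `value`; zero cells are omitted. A compact
#' text serialization for multi-species stacks.
#'
#' @param stack Cells-x-species matrix with species-id column names.
#' @param path Output CSV path.
#' @export
write_stack_csv <- function(stack, path) {
  idx <- which(stack > 0, arr.ind = TRUE)
  readr::write_csv(
    tibble::tibble(cell = idx[, 1],
                   species_id = colnames(stack)[idx[, 2]],
                   value = stack[idx]),
    path)
  invisible(path)
}

#' Read a sparse long-format stack CSV
#'
#' @param path CSV path from [write_stack_csv()].
#' @param n_cells Number of grid cells (rows of the resulting matrix).
#' @param species_ids Optional species order; defaults to order of first
#'   appearance.
#' @return A cells-x-species matrix.
#' @export
read_stack_csv <- function(path, n_cells, species_ids = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  species_ids <- species_ids %||% unique(df$species_id)
  m <- matrix(0, n_cells, length(species_ids),
              dimnames = list(NULL, species_ids))
  m[cbind(df$cell, match(df$species_id, species_ids))] <- df$value
  m
}

#' Write a landscape bundle to a directory of plain-text files
#'
#' Rasters go to ASCII grids, stacks to sparse CSVs, the species and trait
#' tables to CSV, and the tree to Newick.
#'
#' @param landscape A [generate_landscape()] result.
#' @param dir Output directory (created if missing).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- landscape$grid
  for (nm in c("coverage", "hfi", "excluded", "subregions_political",
               "subregions_ecological")) {
    write_raster_ascii(landscape[[nm]], file.path(dir, paste0(nm, ".asc")), g)
  }
  write_stack_csv(landscape$suitability_current,
                  file.path(dir, "suitability_current.csv"))
  write_stack_csv(landscape$suitability_future,
                  file.path(dir, "suitability_future.csv"))
  readr::write_csv(landscape$species, file.path(dir, "species.csv"))
  readr::write_csv(landscape$traits, file.path(dir, "traits.csv"))
  ape::write.tree(landscape$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' Write a protection report as tidy CSVs
#'
#' One file with a row per species, one with the per-group summaries.
#'
#' @param report A `protection_report`.
#' @param path_species,path_groups Output CSV paths (the group file is
#'   optional).
#' @export
write_protection_report <- function(report, path_species,
                                    path_groups = NULL) {
  readr::write_csv(report$species, path_species)
  if (!is.null(path_groups)) readr::write_csv(report$by_group, path_groups)
  invisible(path_species)
}
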