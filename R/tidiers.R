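# broom-style tidiers for the package's result objects.

#' Tidy a rank map into one row per ranked cell
#'
#' @param x A `rank_result`.
#' @param grid Optional [grid_def()] to add `row`/`col` columns.
#' @param ... Unused.
#' @return A tibble `cell`, (`row`, `col`,) `rank`, `mask_class`,
#'   (`subregion`).
#' @export
tidy.rank_result <- function(x, grid = NULL, ...) {
  out <- tibble::tibble(
    cell = seq_along(x$rank),
    rank = x$rank,
    mask_class = factor(x$mask$class, levels = 0:2,
                        labels = c("excluded", "free", "protected"))
  )
  if (!is.null(x$domains)) out$subregion <- x$domains
  if (!is.null(grid)) {
    out$row <- cell_row(out$cell, grid$nrow)
    out$col <- cell_col(out$cell, grid$nrow)
    out <- dplyr::relocate(out, "row", "col", .after = "cell")
  }
  dplyr::filter(out, !is.na(.data$rank))
}

#' @export
glance.rank_result <- function(x, ...) {
  tibble::tibble(n_ranked = x$meta$n_ranked, rule = x$meta$rule,
                 tie_break = x$meta$tie_break,
                 n_protected = sum(x$mask$class == MASK_PROTECTED),
                 stitched = !is.null(x$domains))
}

#' Tidy a protection report into one row per species
#'
#' @param x A `protection_report`.
#' @param ... Unused.
#' @return The per-species tibble (`species_id`, `range_size`, `target`,
#'   `protected_fraction`, `protected`, plus any grouping columns).
#' @export
tidy.protection_report <- function(x, ...) x$species

#' One-row summary of a protection report
#'
#' @param x A `protection_report`.
#' @param ... Unused.
#' @return Tibble with `n_species`, `n_protected`, `spi`.
#' @export
glance.protection_report <- function(x, ...) {
  tibble::tibble(n_species = x$n_species, n_protected = x$n_protected,
                 spi = x$spi)
}

#' Tidy a scenario suite into its per-scenario summary
#'
#' @param x A `scenario_suite`.
#' @param ... Unused.
#' @return The `summary` tibble (one row per scenario).
#' @export
tidy.scenario_suite <- function(x, ...) x$summary

#' @export
glance.scenario_suite <- function(x, ...) {
  tibble::tibble(n_scenarios = nrow(x$scenarios),
                 protect_fraction = x$manifest$protect_fraction,
                 rule = x$manifest$rule,
                 reference = x$manifest$reference,
                 baseline_spi = x$baseline$spi,
                 stress = if (is.null(x$ordination)) NA_real_ else
                   x$ordination$stress)
}

#' @export
tidy.scenario_ordination <- function(x, ...) x$coords
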