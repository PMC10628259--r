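# Selection scoring: probabilistic range sizes, log-linear rarity-scaled
# protection targets, a modified Species Protection Index (SPI),
# weighted-endemism capture, and trade-offs against a reference scenario.

#' Probabilistic range size of each species
#'
#' A species' range is the sum of its suitability values over the evaluation
#' domain (so the "range" of a probabilistic distribution is its expected
#' occupied area, not a thresholded polygon).
#'
#' @param suitability Cells-x-species matrix in \[0,1\].
#' @param domain Optional integer/logical index of evaluation cells
#'   (e.g. the non-excluded cells); default all cells.
#' @return Named numeric vector of range sizes.
#' @export
range_size <- function(suitability, domain = NULL) {
  if (is.null(dim(suitability))) suitability <- cbind(sp = suitability)
  if (!is.null(domain)) suitability <- suitability[domain, , drop = FALSE]
  if (nrow(suitability) == 0) abort("empty evaluation domain")
  colSums(suitability)
}

#' Log-linear species-specific protection targets
#'
#' Rarity-scaled targets in the Species Protection Index tradition: the
#' commonest decile of species (range at or above the 90th percentile) needs
#' only `floor_target` (10%) of its range protected; the rarest decile
#' (at or below the 10th percentile) needs all of it; in between the target
#' falls linearly in `log(R)`:
#' \deqn{T(R) = 1 + (0.1 - 1)\frac{\ln R - \ln R_{10}}{\ln R_{90} - \ln R_{10}}}
#' Percentiles use linear interpolation between order statistics
#' (`quantile` type 7).
#'
#' @param range_sizes Positive numeric vector of per-species range sizes.
#' @param floor_target Target for the commonest species. Default 0.10.
#' @param lower_pct,upper_pct Percentile pivots. Defaults 0.10 and 0.90.
#' @return Numeric vector of targets in `[floor_target, 1]`.
#' @export
spi_targets <- function(range_sizes, floor_target = 0.10,
                        lower_pct = 0.10, upper_pct = 0.90) {
  if (any(range_sizes <= 0)) abort("all range sizes must be positive")
  if (length(range_sizes) < 10) {
    warn("fewer than 10 species: percentile pivots are unstable")
  }
  r_lo <- quantile(range_sizes, lower_pct, type = 7, names = FALSE)
  r_hi <- quantile(range_sizes, upper_pct, type = 7, names = FALSE)
  if (r_lo == r_hi) {
    warn("degenerate percentile pivots (R10 == R90): mid-species get the floor target")
    return(ifelse(range_sizes < r_lo, 1, floor_target))
  }
  t <- 1 + (floor_target - 1) * (log(range_sizes) - log(r_lo)) /
    (log(r_hi) - log(r_lo))
  pmin(pmax(t, floor_target), 1)
}

#' Assess species protection under a selection
#'
#' Computes every species' protected range fraction
#' \eqn{f_j = \sum_{i \in sel} p_{ij} / R_j}, flags species whose fraction
#' meets or surpasses their target as "protected", and aggregates the
#' Species Protection Index (percentage of species protected), overall and
#' within any grouping columns supplied in `species`.
#'
#' @param suitability Cells-x-species matrix used for evaluation (typically
#'   current-climate suitability).
#' @param selection Logical selection per cell.
#' @param targets Per-species targets from [spi_targets()].
#' @param species Optional tibble with `species_id` plus grouping columns
#'   (e.g. `kingdom`, `group`, `status_national`, `status_global`).
#' @param domain Optional evaluation-domain index (default all cells).
#'   Species with zero range in the domain are dropped from the SPI
#'   denominator with a warning.
#' @return An object of class `protection_report`: list with `species` (a
#'   per-species tibble: `species_id`, `range_size`, `target`,
#'   `protected_fraction`, `protected`), `spi` (overall percentage), and
#'   `by_group` (tibble of per-group SPI for each grouping column).
#' @export
assess_protection <- function(suitability, selection, targets,
                              species = NULL, domain = NULL) {
  stopifnot(nrow(suitability) == length(selection))
  domain <- domain %||% seq_len(nrow(suitability))
  R <- range_size(suitability, domain)
  if (length(targets) != length(R)) {
    abort("`targets` length must match the number of species")
  }
  absent <- R == 0
  if (any(absent)) {
    warn(sprintf("%d species absent from the domain were dropped from SPI",
                 sum(absent)))
  }
  sel_dom <- intersect(which(as.logical(selection)), domain)
  prot_sum <- if (length(sel_dom) > 0) {
    colSums(suitability[sel_dom, , drop = FALSE])
  } else {
    numeric(ncol(suitability))
  }
  ids <- colnames(suitability) %||% sprintf("sp%04d", seq_along(R))
  tbl <- tibble::tibble(
    species_id = ids,
    range_size = unname(R),
    target = unname(targets),
    protected_fraction = unname(ifelse(R > 0, prot_sum / R, NA_real_))
  )
  tbl$protected <- tbl$protected_fraction >= tbl$target
  tbl <- tbl[!absent, ]

  if (!is.null(species)) {
    tbl <- dplyr::left_join(tbl, species, by = "species_id")
  }
  spi <- 100 * mean(tbl$protected)

  group_cols <- intersect(c("kingdom", "group", "status_national",
                            "status_global"), names(tbl))
  by_group <- purrr::map(group_cols, function(gc) {
    tbl |>
      dplyr::group_by(level = .data[[gc]]) |>
      dplyr::summarise(n_species = dplyr::n(),
                       n_protected = sum(.data$protected),
                       spi = 100 * mean(.data$protected), .groups = "drop") |>
      dplyr::mutate(grouping = gc, .before = 1)
  }) |> dplyr::bind_rows()

  structure(list(species = tbl, spi = spi, by_group = by_group,
                 n_species = nrow(tbl), n_protected = sum(tbl$protected)),
            class = "protection_report")
}

#' @export
print.protection_report <- function(x, ...) {
  cat(sprintf("<protection_report> SPI %.1f%% (%d of %d species protected)\n",
              x$spi, x$n_protected, x$n_species))
  invisible(x)
}

#' Weighted endemism surface
#'
#' Per-cell sum over species of (cell suitability / species range size), so
#' every species contributes exactly 1 in total across the domain and the
#' surface integrates to the number of species. The share of this surface
#' inside a selection is the "percentage of biodiversity" the selection
#' captures.
#'
#' @param suitability Cells-x-species matrix.
#' @param domain Optional evaluation-domain index; cells outside get `NA`.
#' @return Numeric per-cell vector (NA outside the domain).
#' @export
weighted_endemism <- function(suitability, domain = NULL) {
  if (is.null(dim(suitability))) suitability <- cbind(sp = suitability)
  domain <- domain %||% seq_len(nrow(suitability))
  R <- range_size(suitability, domain)
  if (any(R == 0)) {
    abort(sprintf("zero range in domain for %d species", sum(R == 0)))
  }
  we <- rep(NA_real_, nrow(suitability))
  we[domain] <- as.vector(suitability[domain, , drop = FALSE] %*% (1 / R))
  we
}

#' Biodiversity capture of a selection
#'
#' Percentage of the weighted-endemism total inside the selection:
#' `100 * sum(WE over selected cells) / n_species`. With an at-risk
#' sub-stack's surface this yields at-risk biodiversity capture.
#'
#' @param we Weighted-endemism vector from [weighted_endemism()].
#' @param selection Logical selection per cell.
#' @param n_species Number of species behind `we` (the surface's total).
#' @return A percentage in \[0, 100\].
#' @export
biodiversity_capture <- function(we, selection, n_species) {
  stopifnot(length(we) == length(selection), n_species > 0)
  100 * sum(we[as.logical(selection)], na.rm = TRUE) / n_species
}

#' Protection trade-off versus a reference scenario
#'
#' Relative protection is the alternative's protection as a percentage of
#' the reference's (`100 * n_alt / n_ref`); the trade-off is its shortfall,
#' `relative_protection - 100` (negative when the alternative protects
#' less). Counts and percentages give identical results since the ratio is
#' scale-invariant.
#'
#' @param n_alt,n_ref Protection achieved by the alternative and reference
#'   scenarios (species counts or percentages); `n_ref` must be positive.
#'   Vectorized.
#' @return A tibble `relative_protection`, `tradeoff` (both percentages).
#' @export
#' @examples
#' tradeoff(40, 80) # reference protects 80, alternative 40: trade-off -50%
tradeoff <- function(n_alt, n_ref) {
  if (any(n_ref <= 0)) abort("`n_ref` must be positive")
  rel <- 100 * n_alt / n_ref
  tibble::tibble(relative_protection = rel, tradeoff = rel - 100)
}

#' Facet (functional or phylogenetic) trade-off of a protection outcome
#'
#' Total facet contribution of the protected species as a percentage of the
#' facet total over all species — e.g. how much of the nation's summed
#' evolutionary distinctiveness sits in protected species.
#'
#' @param protected_flags Logical per species.
#' @param contributions Nonnegative per-species facet contributions, aligned
#'   with `protected_flags`.
#' @return A percentage in \[0, 100\].
#' @export
facet_tradeoff <- function(protected_flags, contributions) {
  check_same_length(protected_flags, contributions, what = "species vectors")
  if (any(contributions < 0)) abort("contributions must be nonnegative")
  tot <- sum(contributions)
  if (tot == 0) abort("all-zero contributions")
  100 * sum(contributions[protected_flags]) / tot
}
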