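# Cross-scenario comparison: overlap classes across selections, pairwise
# Pearson correlation of rank maps, and non-metric multidimensional scaling
# of scenarios (sites = scenarios, species = cells).

#' Classify cells by how many scenario selections contain them
#'
#' With `n` selections, a cell selected by all of them is class `"All"`, by
#' at least half (`k >= ceiling((n+1)/2)`, i.e. at least 7 of 13) `"Most"`,
#' by at least one but fewer than half `"Some"`, and by none `"No"`. The
#' summary reports the share of evaluated land in each class; when a
#' weighted-endemism surface is supplied it also reports each class's
#' biodiversity capture.
#'
#' @param selections Named list of logical selection vectors on one grid.
#' @param mask Optional `mask_stack`; classes are reported over non-excluded
#'   cells only.
#' @param we Optional weighted-endemism vector (total biodiversity).
#' @param we_at_risk Optional weighted-endemism vector of the at-risk
#'   sub-stack.
#' @param n_species,n_species_at_risk Species counts behind `we` and
#'   `we_at_risk` (needed to express capture as a percentage).
#' @return List with `class` (factor per cell: No/Some/Most/All, `NA` for
#'   excluded), `count` (integer per cell), and `summary` (tibble per class:
#'   `n_cells`, `pct_land`, optional `pct_biodiversity`, `pct_at_risk`).
#' @export
overlap_classes <- function(selections, mask = NULL, we = NULL,
                            we_at_risk = NULL, n_species = NULL,
                            n_species_at_risk = NULL) {
  if (length(selections) < 2) abort("need at least 2 selections")
  lens <- vapply(selections, length, integer(1))
  if (length(unique(lens)) != 1) abort("selections on mismatched grids")
  n <- length(selections)
  count <- Reduce(`+`, lapply(selections, as.integer))
  keep <- if (is.null(mask)) rep(TRUE, lens[1]) else mask$class != MASK_EXCLUDED
  half <- ceiling((n + 1) / 2)
  cls <- rep(NA_character_, lens[1])
  cls[keep] <- dplyr::case_when(
    count[keep] == n ~ "All",
    count[keep] >= half ~ "Most",
    count[keep] >= 1 ~ "Some",
    TRUE ~ "No"
  )
  cls <- factor(cls, levels = c("No", "Some", "Most", "All"))

  summary <- tibble::tibble(class = factor(levels(cls), levels = levels(cls))) |>
    dplyr::mutate(n_cells = as.integer(table(cls)[as.character(.data$class)]),
                  pct_land = 100 * .data$n_cells / sum(keep))
  capture_col <- function(wev, ns) {
    vapply(levels(cls), function(lv) {
      biodiversity_capture(wev, !is.na(cls) & cls == lv, ns)
    }, numeric(1))
  }
  if (!is.null(we)) {
    stopifnot(!is.null(n_species))
    summary$pct_biodiversity <- capture_col(we, n_species)
  }
  if (!is.null(we_at_risk)) {
    stopifnot(!is.null(n_species_at_risk))
    summary$pct_at_risk <- capture_col(we_at_risk, n_species_at_risk)
  }
  list(class = cls, count = count, summary = summary)
}

#' Pairwise Pearson correlation of scenario rank maps
#'
#' Pearson correlation of cellwise rank values over the common non-excluded
#' domain for every pair of scenarios, with two-sided test p-values. A
#' constant map has no defined correlation and is reported as `NA` with a
#' message.
#'
#' @param rankmaps Named list of `rank_result` objects (or plain numeric rank
#'   vectors) on one grid.
#' @return List with `r` (symmetric correlation matrix, unit diagonal) and
#'   `pairs` (tibble: `a`, `b`, `r`, `p_value`, `significant`).
#' @export
pairwise_correlation <- function(rankmaps) {
  if (length(rankmaps) < 2) abort("need at least 2 rank maps")
  vecs <- lapply(rankmaps, function(x) {
    if (inherits(x, "rank_result")) x$rank else as.numeric(x)
  })
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1) abort("rank maps on mismatched grids")
  common <- Reduce(`&`, lapply(vecs, function(v) !is.na(v)))
  m <- vapply(vecs, function(v) v[common], numeric(sum(common)))
  nm <- names(rankmaps) %||% paste0("scenario", seq_along(rankmaps))
  colnames(m) <- nm

  k <- ncol(m)
  r <- diag(1, k); dimnames(r) <- list(nm, nm)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) {
        inform(sprintf("constant rank map in pair (%s, %s): correlation undefined",
                       nm[i], nm[j]))
        r[i, j] <- r[j, i] <- NA_real_
        rows[[length(rows) + 1]] <- tibble::tibble(
          a = nm[i], b = nm[j], r = NA_real_, p_value = NA_real_,
          significant = NA)
        next
      }
      ct <- suppressWarnings(cor.test(m[, i], m[, j]))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      rows[[length(rows) + 1]] <- tibble::tibble(
        a = nm[i], b = nm[j], r = unname(ct$estimate),
        p_value = ct$p.value, significant = ct$p.value < 0.05)
    }
  }
  list(r = r, pairs = dplyr::bind_rows(rows))
}

#' Ordinate scenarios by non-metric multidimensional scaling
#'
#' Treats each scenario's selection as a site and each cell as a species:
#' builds the binary scenario-by-cell membership matrix, computes pairwise
#' Bray-Curtis dissimilarities, and finds a k-dimensional non-metric
#' embedding minimizing Kruskal stress (via `vegan::metaMDS`). Coordinates
#' are defined up to rotation and reflection. Identical scenarios produce
#' zero dissimilarities, which are nudged by a tiny seeded jitter so the
#' embedding remains defined.
#'
#' @param selections Named list of logical selection vectors on one grid.
#' @param k Embedding dimension. Default 2.
#' @param distance Dissimilarity index passed to `vegan::vegdist`.
#'   Default `"bray"`.
#' @param seed Seed for the embedding's random starts (and the zero-distance
#'   jitter, if needed).
#' @return Object of class `scenario_ordination`: list with `coords`
#'   (tibble `scenario`, `axis1`, ..., `axisk`), `stress`, `k`, `distance`.
#' @export
ordinate_scenarios <- function(selections, k = 2, distance = "bray",
                               seed = 1L) {
  if (length(selections) < 4) {
    abort("need at least 4 scenarios for a meaningful embedding")
  }
  m <- do.call(rbind, lapply(selections, as.integer))
  rownames(m) <- names(selections) %||% paste0("scenario", seq_along(selections))
  d <- vegan::vegdist(m, method = distance)
  if (any(d == 0)) {
    inform(sprintf("zero dissimilarities jittered (seed %d)", seed))
    eps <- min(d[d > 0], 1) * 1e-6
    d[d == 0] <- with_seed(seed, runif(sum(d == 0), 0, eps))
  }
  fit <- with_seed(seed, vegan::metaMDS(d, k = k, trymax = 20, trace = 0))
  coords <- tibble::as_tibble(fit$points, .name_repair = "minimal")
  names(coords) <- paste0("axis", seq_len(ncol(coords)))
  coords <- dplyr::bind_cols(tibble::tibble(scenario = rownames(m)), coords)
  structure(list(coords = coords, stress = fit$stress, k = k,
                 distance = distance),
            class = "scenario_ordination")
}

#' @export
print.scenario_ordination <- function(x, ...) {
  cat(sprintf("<scenario_ordination> %d scenarios, k = %d, stress = %.3f\n",
              nrow(x$coords), x$k, x$stress))
  invisible(x)
}

#' @export
glance.scenario_ordination <- function(x, ...) {
  tibble::tibble(n_scenarios = nrow(x$coords), k = x$k, stress = x$stress,
                 distance = x$distance)
}
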