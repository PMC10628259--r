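# Per-species feature layers and scenario weights: ensemble averaging of
# model projections, climate "win-win" combination of current and future
# layers, kingdom-balanced weights, at-risk subsets, and transnational
# endemism shares.

#' Weighted ensemble average of two model projections
#'
#' Cellwise weighted mean of two aligned rasters (or stacks), e.g. averaging
#' a boosted-regression-tree projection with a maximum-entropy projection at
#' weights 0.7/0.3.
#'
#' @param pred_a,pred_b Aligned numeric vectors or matrices.
#' @param weights Two nonnegative weights summing to 1. Default `c(0.7, 0.3)`.
#' @return The weighted mean, same shape as the inputs.
#' @export
ensemble_average <- function(pred_a, pred_b, weights = c(0.7, 0.3)) {
  if (length(pred_a) != length(pred_b) ||
      !identical(dim(pred_a), dim(pred_b))) {
    abort("misaligned rasters in ensemble_average")
  }
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    abort("`weights` must be two nonnegative values summing to 1")
  }
  weights[1] * pred_a + weights[2] * pred_b
}

#' Combine current and future suitability into a climate "win-win" layer
#'
#' Builds the prioritizer's per-species input by over-weighting cells that are
#' suitable both now and under future climate (candidate climate refugia,
#' where presence is least uncertain), keeping current-only cells at an
#' intermediate level, and down-weighting future-only cells (where eventual
#' occupancy is most uncertain):
#'
#' \deqn{c = w_{both} \min(cur, fut) + w_{now} \, cur + w_{fut} \, fut}
#'
#' then rescaled per species so the maximum cell equals 1. The coefficients
#' must satisfy `w_both > w_now > w_fut > 0`, which guarantees the ordering
#' contract: at equal underlying suitability, overlap cells score higher than
#' current-only cells, which score higher than future-only cells, which score
#' above zero.
#'
#' @param current,future Aligned cells-x-species matrices (or single vectors)
#'   in \[0,1\].
#' @param coeffs Named or positional coefficients `c(both, now, fut)`.
#'   Default `c(0.5, 0.35, 0.15)`.
#' @return A matrix (or vector) of combined scores with per-species maximum 1
#'   (all-zero species stay zero); attribute `coeffs` records the weights.
#' @export
winwin_combine <- function(current, future, coeffs = c(both = 0.5, now = 0.35,
                                                       fut = 0.15)) {
  if (length(current) != length(future) ||
      !identical(dim(current), dim(future))) {
    abort("misaligned rasters in winwin_combine")
  }
  if (length(coeffs) != 3) abort("`coeffs` must have three elements")
  if (!(coeffs[1] > coeffs[2] && coeffs[2] > coeffs[3] && coeffs[3] > 0)) {
    abort("coefficient ordering violated: need w_both > w_now > w_fut > 0")
  }
  c_raw <- coeffs[[1]] * pmin(current, future) + coeffs[[2]] * current +
    coeffs[[3]] * future
  if (is.matrix(c_raw)) {
    mx <- apply(c_raw, 2, max)
    mx[mx == 0] <- 1
    out <- sweep(c_raw, 2, mx, "/")
  } else {
    mx <- max(c_raw)
    out <- if (mx > 0) c_raw / mx else c_raw
  }
  attr(out, "coeffs") <- coeffs
  out
}

#' Rebalance species weights so each kingdom receives an equal total
#'
#' Rescales weights within each kingdom so that kingdom totals are equal (or
#' match supplied totals) while preserving relative weights within kingdoms.
#' This is how a multi-kingdom prioritization avoids being dominated by the
#' most speciose kingdom.
#'
#' @param weights A data frame with columns `species_id`, `kingdom`, `w`.
#' @param kingdom_totals Optional named vector of per-kingdom totals; default
#'   gives every kingdom present a total of 1.
#' @return The weights tibble with `w` rescaled.
#' @export
#' @examples
#' w <- tibble::tibble(species_id = c("v1", "v2", "p1", "p2", "p3", "p4"),
#'                     kingdom = rep(c("vertebrate", "plant"), c(2, 4)),
#'                     w = 1)
#' kingdom_balance(w) # vertebrates 0.5 each, plants 0.25 each
kingdom_balance <- function(weights, kingdom_totals = NULL) {
  stopifnot(all(c("species_id", "kingdom", "w") %in% names(weights)))
  if (any(weights$w < 0)) abort("weights must be nonnegative")
  ks <- unique(weights$kingdom)
  if (is.null(kingdom_totals)) {
    kingdom_totals <- setNames(rep(1, length(ks)), ks)
  }
  if (!all(ks %in% names(kingdom_totals))) {
    abort("`kingdom_totals` missing a kingdom present in `weights`")
  }
  sums <- tapply(weights$w, weights$kingdom, sum)
  if (any(sums == 0)) {
    abort(sprintf("kingdom(s) with all-zero weights: %s",
                  paste(names(sums)[sums == 0], collapse = ", ")))
  }
  weights |>
    dplyr::mutate(
      w = .data$w / as.vector(sums[.data$kingdom]) *
        as.vector(kingdom_totals[.data$kingdom])
    ) |>
    tibble::as_tibble()
}

# status values counting as "at risk" under each assessment scheme
at_risk_statuses <- list(
  national = c("special_concern", "threatened", "endangered"),
  global = c("vulnerable", "endangered", "critically_endangered")
)

#' Subset a weight table to at-risk species
#'
#' Keeps only species whose status under the chosen assessment scheme is in
#' that scheme's at-risk list (national scheme: special concern, threatened,
#' endangered; global scheme: vulnerable, endangered, critically endangered),
#' then rebalances weights across the kingdoms still present.
#'
#' @param weights Data frame with `species_id`, `kingdom`, `w`, and a status
#'   column `status_national` or `status_global`.
#' @param scheme `"national"` or `"global"`.
#' @param include Optional character vector overriding the scheme's status
#'   inclusion list.
#' @return The filtered, kingdom-rebalanced weights tibble.
#' @export
subset_by_status <- function(weights, scheme = c("national", "global"),
                             include = NULL) {
  scheme <- match.arg(scheme)
  col <- paste0("status_", scheme)
  if (!col %in% names(weights)) abort(sprintf("missing column `%s`", col))
  include <- include %||% at_risk_statuses[[scheme]]
  out <- weights[weights[[col]] %in% include, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(sprintf("no species at risk under the %s scheme: scenario undefined",
                  scheme))
  }
  kingdom_balance(tibble::as_tibble(out))
}

#' Transnational endemism share of each species
#'
#' Fraction of a species' total (e.g. continental) range that falls inside the
#' focal planning region: `sum(focal suitabilities) / sum(total suitabilities)`.
#' Used to weight species by how much of their global distribution the focal
#' nation is responsible for.
#'
#' @param focal_stack,total_stack Cells-x-species suitability matrices with
#'   identical species columns; the focal stack covers a sub-extent of the
#'   total stack (so per-species focal sums cannot exceed total sums).
#' @return Named numeric vector of shares in \[0,1\].
#' @export
endemism_weight <- function(focal_stack, total_stack) {
  if (ncol(focal_stack) != ncol(total_stack)) {
    abort("stacks must have the same species columns")
  }
  tot <- colSums(total_stack)
  if (any(tot == 0)) {
    abort(sprintf("zero total range for species: %s",
                  paste(colnames(total_stack)[tot == 0], collapse = ", ")))
  }
  share <- colSums(focal_stack) / tot
  if (any(share > 1 + 1e-9)) {
    abort("focal range exceeds total range; stacks are inconsistent")
  }
  pmin(share, 1)
}
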