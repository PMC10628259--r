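# Greedy marginal-loss spatial prioritization (core-area Zonation family)
# with a hierarchical protected-area mask and optional independent
# per-subregion prioritization stitched to one map.

MASK_EXCLUDED <- 0L
MASK_FREE <- 1L
MASK_PROTECTED <- 2L

#' Classify cells into excluded / free / protected
#'
#' A cell is excluded when its excluded flag is set or its human-footprint
#' value is strictly above `hfi_threshold`; otherwise it is protected when
#' its fractional protected-area coverage is at least `protected_threshold`
#' (inclusive), and free otherwise.
#'
#' @param coverage Fractional protected-area coverage per cell, in \[0,1\].
#' @param hfi Human-footprint value per cell (>= 0).
#' @param excluded Binary per-cell exclusion flag (e.g. land unavailable for
#'   new protection).
#' @param protected_threshold Coverage at or above which a cell counts as
#'   protected. Default 0.43.
#' @param hfi_threshold Human-footprint value strictly above which a cell is
#'   excluded. Default 10.
#' @return An object of class `mask_stack`: list with `class` (integer vector;
#'   0 excluded, 1 free, 2 protected) and the thresholds used.
#' @export
coverage_to_class <- function(coverage, hfi, excluded,
                              protected_threshold = 0.43, hfi_threshold = 10) {
  check_same_length(coverage, hfi, excluded)
  cls <- rep(MASK_FREE, length(coverage))
  cls[coverage >= protected_threshold] <- MASK_PROTECTED
  cls[excluded == 1 | hfi > hfi_threshold] <- MASK_EXCLUDED
  structure(list(class = as.integer(cls),
                 protected_threshold = protected_threshold,
                 hfi_threshold = hfi_threshold),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  tb <- table(factor(x$class, levels = 0:2,
                     labels = c("excluded", "free", "protected")))
  cat("<mask_stack>", paste(sprintf("%s: %d", names(tb), as.integer(tb)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Marginal loss of removing each remaining cell
#'
#' The per-cell loss the greedy prioritizer minimizes at each step. With
#' species weights \eqn{w_j}, feature values \eqn{c_{ij}} and remaining
#' species totals \eqn{Q_j = \sum_{i \in remaining} c_{ij}}:
#' \describe{
#'   \item{`"caz"` (core-area)}{\eqn{\delta_i = \max_j w_j c_{ij} / Q_j} —
#'     a cell is as valuable as it is irreplaceable for its single most
#'     dependent species.}
#'   \item{`"abf"` (additive benefit)}{\eqn{\delta_i = \sum_j w_j c_{ij} / Q_j}.}
#' }
#' Species with \eqn{Q_j = 0} contribute nothing.
#'
#' @param features Cells-x-species matrix of nonnegative feature values.
#' @param weights Per-species nonnegative weights.
#' @param remaining Integer vector of remaining cell indices (rows of
#'   `features`); default all cells.
#' @param rule `"caz"` or `"abf"`.
#' @return Numeric vector of losses, one per remaining cell (in the order of
#'   `remaining`).
#' @export
marginal_loss <- function(features, weights, remaining = NULL,
                          rule = c("caz", "abf")) {
  rule <- match.arg(rule)
  remaining <- remaining %||% seq_len(nrow(features))
  if (length(remaining) == 0) abort("empty remaining set")
  Q <- colSums(features[remaining, , drop = FALSE])
  ratio <- sweep(features[remaining, , drop = FALSE], 2,
                 ifelse(Q > 0, Q, Inf), "/")
  ratio <- sweep(ratio, 2, weights, "*")
  if (rule == "caz") {
    apply(ratio, 1, function(r) if (all(r == 0)) 0 else max(r))
  } else {
    rowSums(ratio)
  }
}

#' Rank cells by iterative greedy marginal-loss removal
#'
#' Repeatedly removes the remaining cell with the smallest marginal loss
#' (ties broken by the lowest cell index, or at random with
#' `tie_break = "random"`), updating remaining species totals after every
#' removal. The hierarchical mask makes all free cells leave before any
#' protected cell, so existing protected land always occupies the top ranks.
#' The rank of a cell is its removal position divided by the number of
#' non-excluded cells, i.e. ranks are a permutation of
#' `{1/N, 2/N, ..., 1}` and 1 marks the highest-priority cell (removed last).
#'
#' @param features Cells-x-species matrix of nonnegative feature values (all
#'   grid cells, excluded rows ignored).
#' @param weights Per-species nonnegative weights.
#' @param mask A [coverage_to_class()] result aligned with `features` rows.
#' @param rule Marginal-loss rule, see [marginal_loss()].
#' @param tie_break `"index"` (deterministic, default) or `"random"`.
#' @param seed Seed for the random tie-break mode.
#' @return An object of class `rank_result`: list with `rank` (numeric per
#'   cell, `NA` for excluded), `order` (cell indices in removal order),
#'   `mask`, `domains` (`NULL` for a whole-domain run), and `meta`.
#' @export
greedy_rank <- function(features, weights, mask, rule = c("caz", "abf"),
                        tie_break = c("index", "random"), seed = 1L) {
  rule <- match.arg(rule)
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(mask, "mask_stack"), nrow(features) == length(mask$class),
            ncol(features) == length(weights))
  if (any(features < 0) || any(weights < 0)) {
    abort("features and weights must be nonnegative")
  }
  avail <- which(mask$class != MASK_EXCLUDED)
  if (!any(mask$class == MASK_FREE)) abort("no free cells to rank")
  if (all(features[avail, ] == 0)) {
    warn("all-zero feature stack: ranks are determined purely by tie-break")
  }

  sub <- features[avail, , drop = FALSE]
  level <- ifelse(mask$class[avail] == MASK_PROTECTED, 1L, 0L)

  if (tie_break == "random") {
    perm <- with_seed(seed, sample.int(length(avail)))
    ord_local <- greedy_order_cpp(sub[perm, , drop = FALSE], weights,
                                  level[perm], if (rule == "caz") 0L else 1L)
    ord <- avail[perm][ord_local + 1L]
  } else {
    ord_local <- greedy_order_cpp(sub, weights, level,
                                  if (rule == "caz") 0L else 1L)
    ord <- avail[ord_local + 1L]
  }

  rank <- rep(NA_real_, nrow(features))
  rank[ord] <- seq_along(ord) / length(ord)
  structure(list(rank = rank, order = ord, mask = mask, domains = NULL,
                 meta = list(rule = rule, tie_break = tie_break,
                             n_ranked = length(ord))),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("<rank_result> %d ranked cells, rule '%s'%s\n",
              x$meta$n_ranked, x$meta$rule,
              if (is.null(x$domains)) "" else
                sprintf(", %d subregions", length(unique(stats::na.omit(x$domains))))))
  invisible(x)
}

#' Independent per-subregion prioritization, stitched to one map
#'
#' Runs [greedy_rank()] separately inside every subregion — each run sees
#' only its own cells, so remaining species totals reflect the species and
#' endemism of that subregion alone — then stitches the per-subregion ranks
#' (each normalized to (0,1\]) into a single map. Thresholding the stitched
#' map at a fraction selects the top fraction of every subregion, which is
#' how an "equal share per region" coordination policy is expressed.
#'
#' @inheritParams greedy_rank
#' @param subregions Integer label per cell; labels must cover all
#'   non-excluded cells. Subregions with no non-excluded cells are skipped
#'   with a warning.
#' @return A `rank_result` whose `domains` field carries the subregion label
#'   of every ranked cell (ranks are a permutation of `{1/N_k, ..., 1}`
#'   within each subregion `k`).
#' @export
subregion_rank <- function(features, weights, mask, subregions,
                           rule = c("caz", "abf"),
                           tie_break = c("index", "random"), seed = 1L) {
  rule <- match.arg(rule)
  tie_break <- match.arg(tie_break)
  stopifnot(length(subregions) == length(mask$class))
  if (any(is.na(subregions[mask$class != MASK_EXCLUDED]))) {
    abort("subregion labels must cover all non-excluded cells")
  }
  rank <- rep(NA_real_, length(mask$class))
  order_all <- list()
  for (k in sort(unique(subregions[mask$class != MASK_EXCLUDED]))) {
    in_k <- subregions == k & mask$class != MASK_EXCLUDED
    if (!any(in_k)) {
      warn(sprintf("subregion %s has no non-excluded cells; skipped", k))
      next
    }
    sub_mask <- structure(
      list(class = ifelse(in_k, mask$class, MASK_EXCLUDED),
           protected_threshold = mask$protected_threshold,
           hfi_threshold = mask$hfi_threshold),
      class = "mask_stack")
    if (!any(sub_mask$class == MASK_FREE)) {
      # fully protected subregion: rank protected cells by index
      idx <- which(in_k)
      rank[idx] <- seq_along(idx) / length(idx)
      order_all[[as.character(k)]] <- idx
      next
    }
    rr <- greedy_rank(features, weights, sub_mask, rule = rule,
                      tie_break = tie_break, seed = seed + k)
    rank[rr$order] <- rr$rank[rr$order]
    order_all[[as.character(k)]] <- rr$order
  }
  domains <- ifelse(is.na(rank), NA_integer_, subregions)
  structure(list(rank = rank, order = unlist(order_all, use.names = FALSE),
                 mask = mask, domains = domains,
                 meta = list(rule = rule, tie_break = tie_break,
                             n_ranked = sum(!is.na(rank)))),
            class = "rank_result")
}

#' Select the top fraction of a rank map
#'
#' Selects the `ceiling(fraction * N)` highest-ranked non-excluded cells
#' (the "protect at least this share" reading of an area target), always
#' *including* already protected areas, which occupy the top ranks by the
#' hierarchy. For a stitched per-subregion map the quota applies within
#' every subregion: exactly `ceiling(fraction * N_k)` cells are selected in
#' each subregion `k`.
#'
#' On a whole-domain hierarchical map a fraction *below* the protected share
#' would have to deselect protected land, which is an error
#' (`over_protected = "error"`, the default there). In a stitched map a
#' single subregion can legitimately hold more protected land than its
#' quota; its selection is then simply its top quota of cells — all of them
#' already protected — and the remaining protected cells sit outside the
#' top fraction (`over_protected = "quota"`, the default for stitched maps,
#' so every subregion contributes exactly its fraction).
#'
#' @param rank A `rank_result`.
#' @param fraction Fraction of non-excluded cells to select, in (0, 1\].
#' @param over_protected `"error"` or `"quota"`; see above. Default depends
#'   on whether the map is stitched.
#' @return Logical selection vector per cell (class `selection`), `FALSE`
#'   for excluded cells; attributes record the fraction.
#' @export
top_fraction <- function(rank, fraction = 0.30, over_protected = NULL) {
  stopifnot(inherits(rank, "rank_result"))
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  over_protected <- over_protected %||%
    (if (is.null(rank$domains)) "error" else "quota")
  over_protected <- match.arg(over_protected, c("error", "quota"))

  sel <- rep(FALSE, length(rank$rank))
  doms <- rank$domains %||% ifelse(is.na(rank$rank), NA_integer_, 1L)
  for (k in sort(unique(stats::na.omit(doms)))) {
    idx <- which(doms == k)
    n_k <- length(idx)
    quota <- ceiling(fraction * n_k - 1e-9) # guard float noise in f * N
    n_prot <- sum(rank$mask$class[idx] == MASK_PROTECTED)
    if (n_prot > quota && over_protected == "error") {
      abort(sprintf(
        "fraction %.2f is below the protected share (%.2f); protected land cannot be deselected",
        fraction, n_prot / n_k))
    }
    take <- idx[order(rank$rank[idx], decreasing = TRUE)[seq_len(quota)]]
    sel[take] <- TRUE
  }
  structure(sel, fraction = fraction, class = c("selection", "logical"))
}

#' Share of each subregion inside a selection
#'
#' For each subregion, the fraction of its non-excluded cells that a
#' selection contains — the regional "commitment" implied by e.g. a national
#' top-30% map.
#'
#' @param selection Logical selection vector (from [top_fraction()]).
#' @param subregions Integer label per cell.
#' @param mask A `mask_stack` (to count non-excluded cells per subregion);
#'   optional, defaults to counting all cells.
#' @return A tibble `subregion`, `n_cells`, `n_selected`, `share`.
#' @export
subregion_share <- function(selection, subregions, mask = NULL) {
  check_same_length(selection, subregions, what = "selection/labels")
  keep <- if (is.null(mask)) rep(TRUE, length(selection)) else
    mask$class != MASK_EXCLUDED
  tibble::tibble(subregion = subregions[keep],
                 selected = as.logical(selection)[keep]) |>
    dplyr::group_by(.data$subregion) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_selected = sum(.data$selected),
                     share = .data$n_selected / .data$n_cells,
                     .groups = "drop")
}
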