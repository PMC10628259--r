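# Facet weights: fair-proportion evolutionary distinctiveness from a
# phylogeny, and functional distinctiveness as leave-one-out convex-hull
# contributions in a two-axis principal-coordinates trait space.

#' Fair-proportion evolutionary distinctiveness
#'
#' Splits every branch length equally among the tips descending from it; a
#' tip's score is the sum of its shares along the path to the root. The
#' scores therefore sum exactly to the total branch length of the tree
#' (a useful conservation identity).
#'
#' @param tree A rooted `ape::phylo` with nonnegative branch lengths and
#'   unique tip labels.
#' @return Named numeric vector of per-tip scores.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' fair_proportion_ed(tr) # A = B = 1.5, C = 2
fair_proportion_ed <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape::phylo")
  if (!ape::is.rooted(tree)) abort("`tree` must be rooted")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  if (is.null(tree$edge.length)) abort("`tree` must have branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths")

  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  # tips below each node
  n_below <- numeric(n_node)
  n_below[seq_len(n_tip)] <- 1
  for (e in seq_len(nrow(tree$edge))) {
    n_below[tree$edge[e, 1]] <- n_below[tree$edge[e, 1]] +
      n_below[tree$edge[e, 2]]
  }
  # accumulate shares root-to-tip (preorder = reverse postorder)
  score <- numeric(n_node)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    score[child] <- score[parent] + tree$edge.length[e] / n_below[child]
  }
  setNames(score[seq_len(n_tip)], tree$tip.label)
}

# shoelace area of the convex hull of 2-D points
hull_area <- function(xy) {
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  p <- xy[h, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

#' Functional distinctiveness from a trait table
#'
#' Per kingdom: Gower distance on the (range-normalized numeric and
#' categorical) traits, principal-coordinates embedding on the first two
#' axes, then each species' leave-one-out contribution to the area of the
#' convex hull occupied in that plane. Interior species contribute nothing
#' (negative deltas clip to zero) and contributions are normalized to sum to
#' 1 within each kingdom, so each kingdom carries equal total weight.
#'
#' The convex-hull area is a deterministic stand-in for a kernel hypervolume:
#' it measures the same occupied-region-of-trait-space notion and is exactly
#' computable at any scale.
#'
#' @param traits Data frame with `species_id`, a grouping column (default
#'   `kingdom`), and one or more trait columns (numeric or
#'   character/factor). Constant trait columns are dropped with a warning.
#' @param group_col Name of the grouping column. Default `"kingdom"`.
#' @return A tibble `species_id`, group column, `fd_contribution` (sums to 1
#'   within each group).
#' @export
functional_distinctiveness <- function(traits, group_col = "kingdom") {
  stopifnot("species_id" %in% names(traits), group_col %in% names(traits))
  trait_cols <- setdiff(names(traits), c("species_id", group_col))
  if (length(trait_cols) == 0) abort("no trait columns")
  const <- vapply(traits[trait_cols],
                  function(x) length(unique(x)) <= 1, logical(1))
  if (all(const)) abort("all trait columns are constant")
  if (any(const)) {
    warn(sprintf("dropping constant trait column(s): %s",
                 paste(trait_cols[const], collapse = ", ")))
    trait_cols <- trait_cols[!const]
  }

  per_group <- function(df) {
    if (nrow(df) < 4) {
      abort(sprintf("group '%s' has fewer than 4 species", df[[group_col]][1]))
    }
    tr <- as.data.frame(df[trait_cols])
    tr[] <- lapply(tr, function(x) if (is.character(x)) factor(x) else x)
    d <- cluster::daisy(tr, metric = "gower")
    emb <- suppressWarnings(cmdscale(d, k = 2))
    if (ncol(emb) < 2) emb <- cbind(emb, 0) # degenerate embedding: 1 real axis
    total <- hull_area(emb)
    delta <- vapply(seq_len(nrow(emb)), function(i) {
      total - hull_area(emb[-i, , drop = FALSE])
    }, numeric(1))
    delta <- pmax(delta, 0)
    if (sum(delta) == 0) {
      warn("degenerate trait space (zero hull area): equal contributions")
      delta <- rep(1, nrow(emb))
    }
    tibble::tibble(species_id = df$species_id,
                   !!group_col := df[[group_col]],
                   fd_contribution = delta / sum(delta))
  }

  traits |>
    dplyr::group_split(.data[[group_col]]) |>
    purrr::map(per_group) |>
    dplyr::bind_rows()
}

#' Phylogenetic distinctiveness contributions per kingdom
#'
#' Fair-proportion evolutionary distinctiveness ([fair_proportion_ed()])
#' normalized to sum to 1 within each kingdom, mirroring the functional
#' contributions so facet scenarios weigh kingdoms evenly.
#'
#' @param tree A rooted `ape::phylo` whose tips are species ids.
#' @param species Data frame with `species_id` and `kingdom`; every tip must
#'   appear. Species missing from the tree are dropped with a warning.
#' @return A tibble `species_id`, `kingdom`, `pd_contribution`.
#' @export
phylogenetic_distinctiveness <- function(tree, species) {
  ed <- fair_proportion_ed(tree)
  miss <- setdiff(species$species_id, names(ed))
  if (length(miss) > 0) {
    warn(sprintf("%d species missing from the tree were dropped", length(miss)))
  }
  species |>
    dplyr::filter(.data$species_id %in% names(ed)) |>
    dplyr::mutate(ed = unname(ed[.data$species_id])) |>
    dplyr::group_by(.data$kingdom) |>
    dplyr::mutate(pd_contribution = .data$ed / sum(.data$ed)) |>
    dplyr::ungroup() |>
    dplyr::select("species_id", "kingdom", "pd_contribution")
}
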