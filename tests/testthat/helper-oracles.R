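# Independent reference implementations used as oracles.

# Naive greedy marginal-loss ranking: at every step, re-evaluate the marginal
# loss of every remaining candidate from scratch and remove the minimum,
# breaking ties by the lowest cell index. Hierarchy levels are processed in
# ascending order. Remaining totals are updated by elementwise subtraction
# (the same operation sequence as the package implementation, so the two
# routes agree bit-for-bit while the delta evaluation and the scan for the
# minimum stay fully independent).
naive_greedy_order <- function(features, weights, level, rule = "caz") {
  n <- nrow(features)
  Q <- colSums(features)
  remaining <- rep(TRUE, n)
  order_out <- integer(0)
  for (lev in sort(unique(level))) {
    candidates <- which(level == lev)
    while (any(remaining[candidates])) {
      live <- candidates[remaining[candidates]]
      deltas <- vapply(live, function(i) {
        contrib <- ifelse(Q > 0, weights * features[i, ] / Q, 0)
        if (rule == "caz") max(contrib, 0) else sum(contrib)
      }, numeric(1))
      pick <- live[which(deltas == min(deltas))[1]] # lowest index among ties
      order_out <- c(order_out, pick)
      Q <- Q - features[pick, ]
      remaining[pick] <- FALSE
    }
  }
  order_out
}

# random small prioritization instance (features, weights, mask)
random_instance <- function(n_cells_max = 100, n_species_max = 10,
                            tie_prone = FALSE, protected_prob = 0.2,
                            excluded_prob = 0.1) {
  n <- sample(4:n_cells_max, 1)
  s <- sample(2:n_species_max, 1)
  f <- matrix(runif(n * s), n, s)
  if (tie_prone) f <- round(f, 1) # coarse values force frequent ties
  f[f < 0.2] <- 0
  w <- runif(s, 0.2, 2)
  cls <- sample(0:2, n, replace = TRUE,
                prob = c(excluded_prob, 1 - excluded_prob - protected_prob,
                         protected_prob))
  if (!any(cls == 1)) cls[sample(n, 2)] <- 1
  mask <- coverage_to_class(coverage = ifelse(cls == 2, 0.5, 0),
                            hfi = rep(0, n),
                            excluded = as.integer(cls == 0))
  list(features = f, weights = w, mask = mask)
}

# small seeded landscape for property tests
small_landscape <- function(seed, rows = 15, cols = 15) {
  generate_landscape(synthetic_config(
    grid_rows = rows, grid_cols = cols,
    n_species_per_group = c(bird = 2, plant = 4, butterfly = 2),
    range_size_lognormal = c(meanlog = 3, sdlog = 0.8),
    shift_cells = 2, seed = seed))
}

expect_selection_contains <- function(selection, cells) {
  expect_true(all(selection[cells]))
}
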