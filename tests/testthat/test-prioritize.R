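test_that("mask classification applies inclusive coverage and strict footprint thresholds", {
  cov <- c(0.43, 0.42, 0.9, 0.0, 0.5)
  hfi <- c(0, 0, 10, 10.01, 11)
  exc <- c(0, 0, 0, 0, 0)
  m <- coverage_to_class(cov, hfi, exc)
  expect_equal(m$class, c(2L, 1L, 2L, 0L, 0L)) # protected, free, protected, excluded x2

  # random inputs equal the per-cell rule oracle
  set.seed(2)
  cov <- runif(500); hfi <- runif(500, 0, 15); exc <- rbinom(500, 1, 0.1)
  m <- coverage_to_class(cov, hfi, exc)
  oracle <- ifelse(exc == 1 | hfi > 10, 0L, ifelse(cov >= 0.43, 2L, 1L))
  expect_identical(m$class, oracle)
  expect_error(coverage_to_class(cov, hfi[1:10], exc), "misaligned")
})

test_that("marginal loss matches hand evaluation on the two-species fixture", {
  f <- matrix(c(1, 0, 0, 0, 0.5, 0.5), 3, 2)
  expect_equal(marginal_loss(f, c(1, 1)), c(1, 0.5, 0.5))
  # a cell holding a species' entire remaining range is maximally irreplaceable
  expect_gte(marginal_loss(f, c(1, 1))[1], 1)
  # a cell with no features has zero loss
  f2 <- rbind(f, 0)
  expect_equal(marginal_loss(f2, c(1, 1))[4], 0)
  # additive-benefit alternative
  expect_equal(marginal_loss(f, c(1, 1), rule = "abf"), c(1, 0.5, 0.5))
  expect_error(marginal_loss(f, c(1, 1), remaining = integer(0)), "empty")
})

test_that("greedy removal order matches the worked fixture step by step", {
  # species A entirely in cell 1; species B split over cells 2 and 3.
  # step 1: losses (1, .5, .5) -> tie between cells 2,3 -> remove cell 2;
  # step 2: B's remaining range is all in cell 3 -> losses (1, 1) -> tie ->
  # remove cell 1; cell 3 survives last. Priority: cell3 > cell1 > cell2.
  f <- matrix(c(1, 0, 0, 0, 0.5, 0.5), 3, 2)
  m <- coverage_to_class(rep(0, 3), rep(0, 3), rep(0, 3))
  r <- greedy_rank(f, c(1, 1), m)
  expect_equal(r$order, c(2L, 1L, 3L))
  expect_equal(r$rank, c(2 / 3, 1 / 3, 1))
})

test_that("greedy ranking equals the naive full-recomputation oracle", {
  set.seed(99)
  for (i in 1:30) {
    inst <- random_instance(n_cells_max = 60, n_species_max = 8,
                            tie_prone = i %% 2 == 0)
    rule <- if (i %% 3 == 0) "abf" else "caz"
    avail <- which(inst$mask$class != 0L)
    lev <- ifelse(inst$mask$class[avail] == 2L, 1L, 0L)
    oracle <- avail[naive_greedy_order(inst$features[avail, , drop = FALSE],
                                       inst$weights, lev, rule)]
    got <- suppressWarnings(
      greedy_rank(inst$features, inst$weights, inst$mask, rule = rule))
    expect_identical(got$order, oracle)
  }
})

test_that("ranks are a permutation of i/N and protected cells always outrank free cells", {
  set.seed(12)
  inst <- random_instance(n_cells_max = 80)
  r <- suppressWarnings(greedy_rank(inst$features, inst$weights, inst$mask))
  ranked <- r$rank[!is.na(r$rank)]
  n <- length(ranked)
  expect_equal(sort(ranked), seq_len(n) / n)
  prot <- inst$mask$class == 2L
  if (any(prot)) {
    expect_gt(min(r$rank[prot]), max(r$rank[inst$mask$class == 1L]))
  }
  expect_true(all(is.na(r$rank[inst$mask$class == 0L])))
})

test_that("a worthless protected cell still outranks every free cell", {
  f <- matrix(runif(20), 10, 2)
  f[4, ] <- 0 # protected cell with zero suitability
  cov <- rep(0, 10); cov[4] <- 1
  m <- coverage_to_class(cov, rep(0, 10), rep(0, 10))
  r <- greedy_rank(f, c(1, 1), m)
  expect_equal(which.max(r$rank), 4L)
})

test_that("all-zero features warn and rank purely by tie-break order", {
  f <- matrix(0, 6, 2)
  m <- coverage_to_class(rep(0, 6), rep(0, 6), rep(0, 6))
  expect_warning(r <- greedy_rank(f, c(1, 1), m), "tie-break")
  expect_equal(r$order, 1:6) # lowest index removed first
})

test_that("random tie-break mode is seeded and reproducible", {
  f <- matrix(0.5, 8, 1)
  m <- coverage_to_class(rep(0, 8), rep(0, 8), rep(0, 8))
  r1 <- suppressWarnings(greedy_rank(f, 1, m, tie_break = "random", seed = 4))
  r2 <- suppressWarnings(greedy_rank(f, 1, m, tie_break = "random", seed = 4))
  r3 <- suppressWarnings(greedy_rank(f, 1, m, tie_break = "random", seed = 5))
  expect_identical(r1$order, r2$order)
  expect_false(identical(r1$order, r3$order))
})

test_that("the trivial partition reproduces the whole-domain ranking exactly", {
  set.seed(21)
  inst <- random_instance(n_cells_max = 50)
  whole <- suppressWarnings(greedy_rank(inst$features, inst$weights, inst$mask))
  one <- suppressWarnings(
    subregion_rank(inst$features, inst$weights, inst$mask,
                   rep(1L, nrow(inst$features))))
  expect_equal(one$rank, whole$rank)
})

test_that("per-subregion selection takes exactly the ceiling quota in each subregion", {
  land <- small_landscape(31, rows = 20, cols = 20)
  m <- coverage_to_class(land$coverage, land$hfi, land$excluded)
  subs <- as.integer(thirty30:::cell_col(seq_len(400), 20) > 10) + 1L
  f <- land$suitability_current
  r <- subregion_rank(f, rep(1, ncol(f)), m, subs)
  sel <- suppressWarnings(top_fraction(r, 0.3))
  for (k in 1:2) {
    n_k <- sum(subs == k & m$class != 0L)
    expect_equal(sum(sel[subs == k]), ceiling(0.3 * n_k))
  }
})

test_that("species confined to one subregion cannot reorder another subregion", {
  set.seed(44)
  n <- 60
  subs <- rep(1:2, each = 30)
  f <- matrix(runif(2 * n), n, 4)
  f[subs == 2, 1] <- 0 # species 1 lives only in subregion 1
  m <- coverage_to_class(rep(0, n), rep(0, n), rep(0, n))
  base <- subregion_rank(f, rep(1, 4), m, subs)
  f2 <- f
  f2[subs == 1, 1] <- f2[subs == 1, 1] * runif(30, 0.1, 2) # perturb it
  pert <- subregion_rank(f2, rep(1, 4), m, subs)
  expect_equal(pert$rank[subs == 2], base$rank[subs == 2])
})

test_that("top-fraction selection counts, hierarchy and nestedness behave", {
  set.seed(3)
  inst <- random_instance(n_cells_max = 40, protected_prob = 0.15)
  r <- suppressWarnings(greedy_rank(inst$features, inst$weights, inst$mask))
  n_avail <- sum(inst$mask$class != 0L)

  expect_equal(sum(top_fraction(r, 1)), n_avail)

  # 10 available cells at fraction 0.25 -> ceiling gives 3 (counting oracle)
  f10 <- matrix(runif(10), 10, 1)
  m10 <- coverage_to_class(rep(0, 10), rep(0, 10), rep(0, 10))
  r10 <- greedy_rank(f10, 1, m10)
  expect_equal(sum(top_fraction(r10, 0.25)), 3)

  # fraction equal to protected share selects exactly the protected cells
  prot <- which(inst$mask$class == 2L)
  if (length(prot) > 0) {
    sel_p <- top_fraction(r, length(prot) / n_avail)
    expect_setequal(which(sel_p), prot)
    # below the protected share: error in hierarchical whole-domain mode
    if (length(prot) > 1) {
      expect_error(top_fraction(r, (length(prot) - 1) / n_avail),
                   "deselect")
    }
  }

  # nestedness across fractions
  s1 <- top_fraction(r, 0.4); s2 <- top_fraction(r, 0.7)
  expect_true(all(which(s1) %in% which(s2)))
})

test_that("subregion shares are exact counting ratios", {
  sel <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  subs <- c(1, 1, 1, 2, 2, 2)
  out <- subregion_share(sel, subs)
  expect_equal(out$share, c(2 / 3, 1 / 3))
  # selection confined to one subregion
  out2 <- subregion_share(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), subs)
  expect_equal(out2$share, c(2 / 3, 0))
})
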