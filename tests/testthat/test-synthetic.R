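test_that("identical config and seed give bit-identical landscapes and occurrences", {
  cfg <- synthetic_config(grid_rows = 25, grid_cols = 25,
                          n_species_per_group = c(bird = 3, plant = 6),
                          seed = 11)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$suitability_current, b$suitability_current)
  expect_identical(a$suitability_future, b$suitability_future)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$species, b$species)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(generate_occurrences(a, 200), generate_occurrences(b, 200))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(grid_rows = 0), "positive")
  expect_error(synthetic_config(protected_fraction = 0.6,
                                excluded_fraction = 0.5), "< 1")
  expect_error(synthetic_config(n_species_per_group = c(dragon = 5)), "groups")
  expect_error(synthetic_config(gradient_strength = -1), "nonnegative")
})

test_that("zero gradient strength gives uniform latitudinal centroid positions", {
  # empirical-CDF (Kolmogorov-Smirnov) check on the generator's latitudinal
  # sampler, two-sided at alpha = 0.01 over 2000 draws
  pos <- thirty30:::with_seed(5, thirty30:::sample_gradient_pos(2000, 0))
  expect_gt(stats::ks.test(pos, "punif")$p.value, 0.01)
  # and a positive gradient concentrates mass toward the southern end
  pos_g <- thirty30:::with_seed(5, thirty30:::sample_gradient_pos(2000, 6))
  expect_lt(mean(pos_g), 0.25)
})

test_that("zero shift makes the future stack identical to the current stack", {
  land <- generate_landscape(synthetic_config(
    grid_rows = 20, grid_cols = 20,
    n_species_per_group = c(plant = 8), shift_cells = 0, seed = 3))
  expect_identical(land$suitability_future, land$suitability_current)
})

test_that("poleward shift moves future range centroids north", {
  land <- generate_landscape(synthetic_config(
    grid_rows = 40, grid_cols = 40,
    n_species_per_group = c(plant = 20), shift_cells = 6, seed = 4))
  centroid_row <- function(v) {
    rows <- thirty30:::cell_row(seq_along(v), 40)
    sum(rows * v) / sum(v)
  }
  shift <- vapply(seq_len(20), function(j) {
    centroid_row(land$suitability_future[, j]) -
      centroid_row(land$suitability_current[, j])
  }, numeric(1))
  expect_gt(median(shift), 1) # truncation at the edge damps the full 6 cells
})

test_that("landscape invariants hold: value range, occupancy, partitions, coverage calibration", {
  land <- generate_landscape(synthetic_config(seed = 2))
  expect_true(all(land$suitability_current >= 0 & land$suitability_current <= 1))
  expect_false(anyNA(land$suitability_current))
  expect_true(all(colSums(land$suitability_current > 0) >= 1))
  n <- length(land$coverage)
  expect_equal(length(land$subregions_political), n)
  expect_false(anyNA(land$subregions_political))
  expect_false(anyNA(land$subregions_ecological))
  # protected share at the 0.43 threshold within 2 percentage points (100x100)
  expect_lt(abs(mean(land$coverage >= 0.43) - 0.15), 0.02)
  # excluded flag share near its setting
  expect_lt(abs(mean(land$excluded == 1) - 0.05), 0.02)
})

test_that("range-size distribution is right-skewed over many species", {
  land <- generate_landscape(synthetic_config(
    grid_rows = 60, grid_cols = 60,
    n_species_per_group = c(plant = 500), seed = 9))
  R <- colSums(land$suitability_current)
  expect_gt(mean(R), median(R))
})

test_that("unbiased occurrence sampling is proportional to suitability", {
  land <- generate_landscape(synthetic_config(
    grid_rows = 12, grid_cols = 12,
    n_species_per_group = c(plant = 3),
    range_size_lognormal = c(meanlog = 3.5, sdlog = 0.3), seed = 6))
  occ <- generate_occurrences(land, n_points = 30000, bias_strength = 0,
                              seed = 21)
  g <- land$grid
  sp <- colnames(land$suitability_current)[1]
  pts <- occ[occ$species_id == sp, ]
  cells <- thirty30:::xy_to_cell(g, pts$x, pts$y)
  p <- land$suitability_current[, 1]
  support <- which(p > 0)
  obs <- tabulate(cells, nbins = length(p))[support]
  # chi-square goodness of fit, lumping low-expectation cells
  expected <- sum(obs) * p[support] / sum(p[support])
  lump <- expected < 5
  obs2 <- obs[!lump]; exp2 <- expected[!lump]
  if (any(lump)) { obs2 <- c(obs2, sum(obs[lump])); exp2 <- c(exp2, sum(expected[lump])) }
  chi <- sum((obs2 - exp2)^2 / exp2)
  p_val <- stats::pchisq(chi, df = length(obs2) - 1, lower.tail = FALSE)
  expect_gt(p_val, 0.001)
  # and all non-erroneous points fall on positive-suitability cells
  expect_true(all(p[cells] > 0))
})

test_that("southward sampling bias shifts occurrences toward low rows", {
  land <- small_landscape(8, rows = 30, cols = 30)
  y0 <- mean(generate_occurrences(land, 4000, bias_strength = 0, seed = 1)$y)
  y3 <- mean(generate_occurrences(land, 4000, bias_strength = 3, seed = 1)$y)
  expect_lt(y3, y0)
})

test_that("erroneous points exist and occurrence draws are seed-deterministic", {
  land <- small_landscape(10)
  a <- generate_occurrences(land, 500, error_fraction = 0.1, seed = 2)
  b <- generate_occurrences(land, 500, error_fraction = 0.1, seed = 2)
  expect_identical(a, b)
  expect_gt(sum(a$erroneous), 0)
})

test_that("the synthetic phylogeny is rooted, binary-rooted and covers all species", {
  land <- small_landscape(12)
  expect_true(ape::is.rooted(land$tree))
  expect_setequal(land$tree$tip.label, land$species$species_id)
})
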