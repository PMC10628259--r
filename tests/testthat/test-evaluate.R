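test_that("range size is the sum of suitabilities over the domain", {
  bin <- matrix(0, 100, 1); bin[1:50, 1] <- 1
  expect_equal(unname(range_size(bin)), 50)
  expect_equal(unname(range_size(matrix(0.2, 10, 1))), 2)
  set.seed(6)
  m <- matrix(runif(60), 20, 3)
  dom <- sample(20, 12)
  expect_equal(unname(range_size(m, dom)), unname(colSums(m[dom, ])))
  expect_error(range_size(m, integer(0)), "empty")
})

test_that("protection targets hit the decile endpoints and log-linear midpoint", {
  # 11 log-spaced ranges: with interpolated percentiles, R10 is the 2nd and
  # R90 the 10th order statistic, and the 6th is their exact geometric mean
  R <- exp(0:10)
  t <- spi_targets(R)
  expect_equal(t[2], 1.0, tolerance = 1e-12)
  expect_equal(t[10], 0.10, tolerance = 1e-12)
  expect_equal(t[6], 0.55, tolerance = 1e-12)
  # species rarer than the pivot also sit at 1; commoner at 0.1
  expect_equal(t[1], 1.0)
  expect_equal(t[11], 0.10)
})

test_that("targets are nonincreasing in range size and clamped to [0.1, 1]", {
  set.seed(11)
  R <- sort(exp(rnorm(150, 3, 2)))
  t <- spi_targets(R)
  expect_true(all(diff(t) <= 1e-12))
  expect_true(all(t >= 0.10 - 1e-12 & t <= 1 + 1e-12))
  expect_error(spi_targets(c(0, 1)), "positive")
  expect_warning(spi_targets(rep(2, 20)), "degenerate")
})

test_that("protection assessment flags species exactly by their targets", {
  # 10-species hand fixture on a 4-cell grid
  suit <- matrix(0, 4, 10, dimnames = list(NULL, paste0("s", 1:10)))
  for (j in 1:10) suit[, j] <- c(j / 10, j / 20, 0, 0.05)
  sel <- c(TRUE, FALSE, FALSE, TRUE) # cells 1 and 4
  R <- colSums(suit)
  targets <- rep(0.6, 10)
  rep_out <- assess_protection(suit, sel, targets)
  f_hand <- (suit[1, ] + suit[4, ]) / R
  expect_equal(rep_out$species$protected_fraction, unname(f_hand))
  expect_equal(rep_out$species$protected, unname(f_hand >= 0.6))
  expect_equal(rep_out$spi, 100 * mean(f_hand >= 0.6))

  # selection of everything protects everyone; empty selection no one
  expect_equal(assess_protection(suit, rep(TRUE, 4), targets)$spi, 100)
  expect_equal(assess_protection(suit, rep(FALSE, 4), targets)$spi, 0)
})

test_that("species absent from the domain are dropped from the SPI denominator", {
  suit <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(
    out <- assess_protection(suit, c(TRUE, FALSE), c(0.5, 0.5), domain = 1:2),
    "absent")
  expect_equal(out$n_species, 1)
})

test_that("per-group summaries count protected species within each group", {
  land <- small_landscape(19)
  m <- coverage_to_class(land$coverage, land$hfi, land$excluded)
  dom <- which(m$class != 0L)
  R <- range_size(land$suitability_current, dom)
  rep_out <- suppressWarnings(assess_protection(
    land$suitability_current, m$class == 2L, spi_targets(R),
    species = land$species, domain = dom))
  kg <- dplyr::filter(rep_out$by_group, grouping == "kingdom")
  expect_equal(sum(kg$n_species), rep_out$n_species)
  expect_equal(sum(kg$n_protected), rep_out$n_protected)
})

test_that("weighted endemism conserves one unit per species", {
  # fixture: species A entirely in cell 1, species B split over cells 2, 3
  f <- matrix(c(1, 0, 0, 0, 0.5, 0.5), 3, 2)
  expect_equal(weighted_endemism(f), c(1, 0.5, 0.5))

  one <- matrix(1 / 7, 7, 1)
  expect_equal(weighted_endemism(one), rep(1 / 7, 7))

  set.seed(14)
  m <- matrix(runif(80), 20, 4)
  expect_equal(sum(weighted_endemism(m)), 4, tolerance = 1e-12)
})

test_that("biodiversity capture is the selected share of the endemism surface", {
  f <- matrix(c(1, 0, 0, 0, 0.5, 0.5), 3, 2)
  we <- weighted_endemism(f)
  expect_equal(biodiversity_capture(we, c(TRUE, FALSE, FALSE), 2), 50)
  expect_equal(biodiversity_capture(we, rep(TRUE, 3), 2), 100)
  expect_equal(biodiversity_capture(we, rep(FALSE, 3), 2), 0)
})

test_that("trade-off formula reproduces its definition and is scale invariant", {
  expect_equal(tradeoff(40, 80)$tradeoff, -50)
  expect_equal(tradeoff(5, 10)$relative_protection, 50)
  expect_equal(tradeoff(7, 7)$tradeoff, 0)
  # counts vs percentages are equivalent
  expect_equal(tradeoff(40, 80)$tradeoff, tradeoff(4.4, 8.8)$tradeoff)
  expect_error(tradeoff(5, 0), "positive")
})

test_that("facet trade-off weighs protected species by their contributions", {
  ed <- fair_proportion_ed(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  # only C protected: 2 of total 5 branch-length units
  expect_equal(facet_tradeoff(c(FALSE, FALSE, TRUE), ed[c("A", "B", "C")]), 40)
  expect_equal(facet_tradeoff(rep(TRUE, 3), ed), 100)
  expect_equal(facet_tradeoff(c(TRUE, FALSE), c(1, 1)), 50)
  expect_error(facet_tradeoff(c(TRUE, FALSE), c(0, 0)), "all-zero")
})

test_that("enlarging a selection never lowers protection metrics", {
  set.seed(15)
  for (i in 1:5) {
    suit <- matrix(runif(200), 50, 4)
    R <- range_size(suit)
    targets <- spi_targets(c(R, exp(runif(16, 0, 5))))[1:4]
    we <- weighted_endemism(suit)
    sel <- rep(FALSE, 50)
    last_spi <- -1; last_cap <- -1; last_f <- rep(-1, 4)
    for (add in split(sample(50), rep(1:5, each = 10))) {
      sel[add] <- TRUE
      rp <- assess_protection(suit, sel, targets)
      cap <- biodiversity_capture(we, sel, 4)
      expect_gte(rp$spi, last_spi)
      expect_gte(cap, last_cap)
      expect_true(all(rp$species$protected_fraction >= last_f - 1e-12))
      last_spi <- rp$spi; last_cap <- cap
      last_f <- rp$species$protected_fraction
    }
  }
})
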