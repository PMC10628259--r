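test_that("thinning keeps one record per species per cell", {
  g <- grid_def(10, 10)
  pts <- tibble::tibble(x = c(0.2, 0.7, 5.5), y = c(0.2, 0.4, 2.5),
                        species_id = c("a", "a", "a"))
  out <- grid_and_thin(pts, g)
  expect_equal(nrow(out), 2) # first two points share cell (1,1)
})

test_that("cell membership is half-open: boundary points split into distinct cells", {
  g <- grid_def(10, 10)
  eps <- 1e-9
  pts <- tibble::tibble(x = c(3 - eps, 3 + eps, 3), y = rep(0.5, 3),
                        species_id = "a")
  out <- grid_and_thin(pts, g)
  expect_equal(sort(unique(out$col)), c(3, 4)) # x = 3 belongs to column 4
})

test_that("thinning equals brute-force binning on random points", {
  g <- grid_def(10, 10)
  set.seed(31)
  pts <- tibble::tibble(x = runif(1000, 0, 10), y = runif(1000, 0, 10),
                        species_id = sample(letters[1:4], 1000, replace = TRUE))
  out <- grid_and_thin(pts, g)
  # independent binning oracle
  oracle <- unique(data.frame(
    species_id = pts$species_id,
    cell = (floor(pts$y) + 1) + floor(pts$x) * 10))
  expect_setequal(paste(out$species_id, out$cell),
                  paste(oracle$species_id, oracle$cell))
  # idempotence: thinning cell centers of the output changes nothing
  centers <- tibble::tibble(x = out$col - 0.5, y = out$row - 0.5,
                            species_id = out$species_id)
  expect_equal(nrow(grid_and_thin(centers, g)), nrow(out))
})

test_that("out-of-grid points are dropped with a message and empty input warns", {
  g <- grid_def(5, 5)
  pts <- tibble::tibble(x = c(1, 99), y = c(1, 99), species_id = "a")
  expect_message(out <- grid_and_thin(pts, g), "dropped 1")
  expect_equal(nrow(out), 1)
  expect_warning(empty <- grid_and_thin(pts[0, ], g), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("knn filter removes exactly the distant point from a cluster", {
  set.seed(5)
  pts <- tibble::tibble(x = c(rnorm(10, 0, 0.5), 50),
                        y = c(rnorm(10, 0, 0.5), 50),
                        species_id = "a")
  # brute-force oracle: mean distance to 3 nearest others
  d <- as.matrix(dist(cbind(pts$x, pts$y))); diag(d) <- Inf
  mean3 <- apply(d, 1, function(r) mean(sort(r)[1:3]))
  thr <- 10
  expect_identical(unname(which(mean3 > thr)), 11L)
  out <- suppressMessages(knn_outlier_filter(pts, max_mean_dist = thr))
  expect_equal(nrow(out), 10)
  expect_false(50 %in% out$x)
})

test_that("infinite threshold is a no-op and small species pass through", {
  pts <- tibble::tibble(x = c(0, 1, 100), y = c(0, 1, 100), species_id = "a")
  expect_identical(knn_outlier_filter(pts, max_mean_dist = Inf), pts)
  expect_identical(knn_outlier_filter(pts, max_mean_dist = 0.001, k = 3), pts)
})

test_that("coincident duplicate outliers are both removed via the k-NN mean", {
  # two copies of a far point: each sees the other at distance 0 but the
  # 3-NN mean still includes cluster points, pushing it past the threshold
  pts <- tibble::tibble(x = c(0, 0.5, 1, 0.2, 60, 60),
                        y = c(0, 0.5, 0, 0.7, 60, 60),
                        species_id = "a")
  d <- as.matrix(dist(cbind(pts$x, pts$y))); diag(d) <- Inf
  mean3 <- apply(d, 1, function(r) mean(sort(r)[1:3]))
  expect_true(all(mean3[5:6] > 20))
  out <- suppressMessages(knn_outlier_filter(pts, max_mean_dist = 20))
  expect_equal(nrow(out), 4)
})

test_that("knn filter output is a subset and monotone in the threshold", {
  set.seed(17)
  for (rep in 1:5) {
    pts <- tibble::tibble(x = runif(40, 0, 20), y = runif(40, 0, 20),
                          species_id = sample(c("a", "b"), 40, replace = TRUE))
    small <- suppressMessages(knn_outlier_filter(pts, max_mean_dist = 2))
    large <- suppressMessages(knn_outlier_filter(pts, max_mean_dist = 6))
    expect_true(all(paste(small$x, small$y) %in% paste(pts$x, pts$y)))
    expect_true(all(paste(small$x, small$y) %in% paste(large$x, large$y)))
  }
})

test_that("per-group thresholds apply via the groups table", {
  pts <- tibble::tibble(x = c(0, 0.5, 1, 0.2, 30, 0, 0.5, 1, 0.2, 30),
                        y = c(0, 0.5, 0, 0.7, 30, 0, 0.5, 0, 0.7, 30),
                        species_id = rep(c("a", "b"), each = 5))
  groups <- tibble::tibble(species_id = c("a", "b"),
                           group = c("bird", "plant"))
  out <- suppressMessages(
    knn_outlier_filter(pts, max_mean_dist = c(bird = 10, plant = 1000),
                       groups = groups))
  expect_equal(sum(out$species_id == "a"), 4) # bird outlier removed
  expect_equal(sum(out$species_id == "b"), 5) # plant threshold huge: kept
  expect_error(knn_outlier_filter(pts, max_mean_dist = c(bird = 10)),
               "groups")
})

test_that("range truncation zeroes outside the polygon and respects the buffer", {
  g <- grid_def(12, 12)
  suit <- matrix(runif(144), 12, 12)
  square <- cbind(c(4, 8, 8, 4), c(4, 4, 8, 8))

  # buffer 0: support equals point-in-polygon (independent oracle: sp)
  out0 <- buffer_range_truncate(suit, square, buffer = 0, grid = g)
  ctr <- thirty30:::cell_center_xy(g, seq_len(144))
  inside <- sp::point.in.polygon(ctr$x, ctr$y, square[, 1], square[, 2]) > 0
  expect_identical(as.vector(out0) == 0 | inside, rep(TRUE, 144))
  expect_equal(as.vector(out0)[inside], as.vector(suit)[inside])

  # buffer 2: support equals containment in the dilated square (oracle:
  # dense boundary sampling + sp point-in-polygon)
  out2 <- buffer_range_truncate(suit, square, buffer = 2, grid = g)
  boundary <- rbind(
    cbind(seq(4, 8, by = 0.01), 4), cbind(8, seq(4, 8, by = 0.01)),
    cbind(seq(8, 4, by = -0.01), 8), cbind(4, seq(8, 4, by = -0.01)))
  mind <- vapply(seq_len(144), function(i) {
    min(sqrt((boundary[, 1] - ctr$x[i])^2 + (boundary[, 2] - ctr$y[i])^2))
  }, numeric(1))
  in_dilated <- inside | mind <= 2 + 1e-6
  expect_identical(as.vector(out2) > 0, as.vector(suit) > 0 & in_dilated)

  # never increases any cell
  expect_true(all(out2 <= suit))

  # whole-grid polygon: identity
  big <- cbind(c(-1, 13, 13, -1), c(-1, -1, 13, 13))
  expect_identical(buffer_range_truncate(suit, big, 0, g), suit)

  # degenerate polygon: all-zero with warning
  expect_warning(z <- buffer_range_truncate(suit, NULL, 1, g), "polygon")
  expect_true(all(z == 0))
})
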