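# Seeded synthetic landscapes with the statistical structure the planning
# analysis assumes: spatially autocorrelated habitat suitability (Gaussian
# range bumps), a strong equatorward richness gradient, heavy-tailed range
# sizes, poleward displacement of future ranges, clustered protected-area
# coverage (~15% of cells at the 0.43 coverage threshold), a human-footprint
# surface, excluded land, and two subregion partitions.

#' Configuration for the synthetic-landscape generator
#'
#' Defines the study conditions for a simulated planning landscape. Defaults
#' describe a 100 x 100 grid with 300 species whose range-size distribution is
#' heavy-tailed (lognormal), richness concentrated toward the southern edge,
#' a 10-cell poleward shift of future ranges, 15% of cells pre-protected in
#' clusters placed away from the richness gradient, and 5% excluded land.
#'
#' @param grid_rows,grid_cols Grid dimensions (positive integers).
#' @param n_species_per_group Named integer vector: species count per
#'   class-level group. Names must be a subset of
#'   `c("bird", "mammal", "amphibian_reptile", "plant", "butterfly")`;
#'   the first three belong to the vertebrate kingdom.
#' @param range_size_lognormal Parameters `c(meanlog, sdlog)` of the lognormal
#'   law for species range area, in cell-count units.
#' @param gradient_strength Nonnegative; 0 means species centroids are uniform
#'   in latitude, larger values concentrate them toward the southern edge
#'   (centroid density proportional to `exp(-gradient_strength * northness)`).
#' @param shift_cells Integer >= 0; poleward displacement (rows) of future
#'   suitability centroids relative to current ones.
#' @param future_width_mult Multiplier on range width in the future layer
#'   (< 1 contracts ranges). Default 1 (pure shift).
#' @param protected_fraction Fraction of cells whose protected-area coverage
#'   reaches the 0.43 "protected" threshold. Default 0.15.
#' @param protected_bias Nonnegative; larger values place protected clusters
#'   farther from the high-richness southern edge. The default (1) spreads
#'   clusters over all latitudes with a moderate northward lean, keeping
#'   every subregion below the 30% target as in the real system.
#' @param excluded_fraction Fraction of cells in the binary excluded layer
#'   (unavailable land other than high human footprint). Default 0.05.
#' @param n_subregions_political,n_subregions_ecological Positive integers.
#' @param sampling_bias_strength Nonnegative; default strength of the
#'   southward observation bias used by [generate_occurrences()].
#' @param seed Integer master seed; fans out to fixed per-component child
#'   seeds so identical configs give bit-identical landscapes.
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(grid_rows = 40, grid_cols = 40,
#'                         n_species_per_group = c(plant = 20, bird = 10),
#'                         seed = 1)
#' land <- generate_landscape(cfg)
synthetic_config <- function(grid_rows = 100, grid_cols = 100,
                             n_species_per_group = c(bird = 40, mammal = 30,
                                                     amphibian_reptile = 30,
                                                     plant = 150, butterfly = 50),
                             range_size_lognormal = c(meanlog = 5, sdlog = 1),
                             gradient_strength = 6,
                             shift_cells = 10,
                             future_width_mult = 1,
                             protected_fraction = 0.15,
                             protected_bias = 1,
                             excluded_fraction = 0.05,
                             n_subregions_political = 6,
                             n_subregions_ecological = 8,
                             sampling_bias_strength = 2,
                             seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) abort("grid dimensions must be positive")
  known <- c("bird", "mammal", "amphibian_reptile", "plant", "butterfly")
  if (is.null(names(n_species_per_group)) ||
      !all(names(n_species_per_group) %in% known)) {
    abort(paste("`n_species_per_group` must be named with groups among:",
                paste(known, collapse = ", ")))
  }
  if (any(n_species_per_group < 1)) abort("each group needs at least 1 species")
  if (protected_fraction < 0 || protected_fraction > 1 ||
      excluded_fraction < 0 || excluded_fraction > 1) {
    abort("fractions must be in [0, 1]")
  }
  if (protected_fraction + excluded_fraction >= 1) {
    abort("protected_fraction + excluded_fraction must be < 1")
  }
  if (gradient_strength < 0 || shift_cells < 0 || protected_bias < 0 ||
      sampling_bias_strength < 0) {
    abort("strength/shift parameters must be nonnegative")
  }
  if (n_subregions_political < 1 || n_subregions_ecological < 1) {
    abort("subregion counts must be positive")
  }
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_species_per_group = n_species_per_group,
         range_size_lognormal = range_size_lognormal,
         gradient_strength = gradient_strength,
         shift_cells = as.integer(shift_cells),
         future_width_mult = future_width_mult,
         protected_fraction = protected_fraction,
         protected_bias = protected_bias,
         excluded_fraction = excluded_fraction,
         n_subregions_political = as.integer(n_subregions_political),
         n_subregions_ecological = as.integer(n_subregions_ecological),
         sampling_bias_strength = sampling_bias_strength,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

kingdom_of_group <- function(group) {
  dplyr::case_when(
    group %in% c("bird", "mammal", "amphibian_reptile") ~ "vertebrate",
    group == "plant" ~ "plant",
    group == "butterfly" ~ "butterfly"
  )
}

# child-seed offsets (fixed so components are independently reproducible)
.seed_offsets <- c(centroids = 101L, ranges = 211L, coverage = 307L,
                   hfi = 401L, excluded = 503L, subregions = 601L,
                   traits = 701L, tree = 809L, status = 907L,
                   occurrences = 1009L)

child_seed <- function(seed, component) {
  (as.integer(seed) %% 1000000L) * 1000L + .seed_offsets[[component]]
}

# inverse-CDF sample of latitudinal position in [0,1]; 0 = southern edge;
# density proportional to exp(-g * x)
sample_gradient_pos <- function(n, g) {
  u <- runif(n)
  if (g == 0) u else -log(1 - u * (1 - exp(-g))) / g
}

# separable Gaussian bump on the grid; returns a column-major raster vector
gaussian_bump <- function(nrow, ncol, crow, ccol, sigma, floor = 0.02) {
  fr <- exp(-((seq_len(nrow) - crow)^2) / (2 * sigma^2))
  fc <- exp(-((seq_len(ncol) - ccol)^2) / (2 * sigma^2))
  v <- as.vector(outer(fr, fc))
  v[v < floor] <- 0
  v
}

# analytic (untruncated) mass of a bump over the infinite discrete plane:
# product of two 1-D sums taken over a window wide enough to converge
bump_total_mass <- function(crow, ccol, sigma) {
  half <- ceiling(6 * sigma)
  sr <- sum(exp(-((seq(floor(crow) - half, ceiling(crow) + half)) - crow)^2 /
                  (2 * sigma^2)))
  sc <- sum(exp(-((seq(floor(ccol) - half, ceiling(ccol) + half)) - ccol)^2 /
                  (2 * sigma^2)))
  sr * sc
}

# clustered [0,1] field: sum of random bumps, monotonically rescaled so that
# `fraction` of cells sit at or above `threshold`
clustered_coverage <- function(nrow, ncol, fraction, threshold, bias,
                               patch_cells = 25) {
  n <- nrow * ncol
  if (fraction <= 0) return(numeric(n))
  k <- max(3L, round(fraction * n / patch_cells))
  crows <- 1 + sample_gradient_pos(k, -bias) * (nrow - 1) # bias>0 -> northern
  ccols <- runif(k, 1, ncol)
  sig <- runif(k, 2, 5)
  field <- numeric(n)
  for (i in seq_len(k)) {
    field <- field + gaussian_bump(nrow, ncol, crows[i], ccols[i], sig[i],
                                   floor = 0)
  }
  q <- stats::quantile(field, 1 - fraction, type = 7, names = FALSE)
  if (q <= 0) q <- max(field) # degenerate: nearly-flat field
  pmin(field / q * threshold, 1)
}

# label raster partitioning the grid into k regions
voronoi_regions <- function(nrow, ncol, k, latitudinal = FALSE) {
  cell <- seq_len(nrow * ncol)
  r <- cell_row(cell, nrow); c <- cell_col(cell, nrow)
  if (latitudinal) {
    # ecozone analogue: latitude-dominated bands with irregular boundaries
    srow <- seq(1, nrow, length.out = k + 1)[-1] - (nrow / k) / 2
    scol <- runif(k, 1, ncol)
    d <- outer(r, srow, function(a, b) (a - b)^2) * 4 +
      outer(c, scol, function(a, b) (a - b)^2) * 0.05
  } else {
    srow <- runif(k, 1, nrow); scol <- runif(k, 1, ncol)
    d <- outer(r, srow, function(a, b) (a - b)^2) +
      outer(c, scol, function(a, b) (a - b)^2)
  }
  max.col(-d, ties.method = "first")
}

#' Generate a complete synthetic planning landscape
#'
#' Produces every input the planning pipeline needs on one shared grid:
#' current and future habitat-suitability stacks, fractional protected-area
#' coverage, a human-footprint surface, excluded land, two subregion
#' partitions, a species table (kingdom, class group, at-risk statuses, and
#' analytic transnational endemism shares), a complete trait table, and a
#' phylogeny with kingdom-level monophyly.
#'
#' Suitability surfaces are isotropic Gaussian bumps around per-species range
#' centroids, with widths set from a lognormal range-area law, which yields
#' spatial autocorrelation and a right-skewed range-size distribution by
#' construction. Future surfaces displace each centroid `shift_cells` rows
#' poleward (and optionally contract widths). Endemism shares compare the
#' within-grid bump mass against the bump's untruncated continental mass, so
#' species whose ranges spill over the southern border get low shares.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `landscape`: a list with elements
#'   `grid` ([grid_def()]), `suitability_current` and `suitability_future`
#'   (cells x species matrices in \[0,1\]), `coverage`, `hfi`, `excluded`,
#'   `subregions_political`, `subregions_ecological` (raster vectors),
#'   `species` (tibble), `traits` (tibble), `tree` (`ape::phylo`), and
#'   `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  R <- config$grid_rows; C <- config$grid_cols
  n <- R * C
  counts <- config$n_species_per_group
  groups <- rep(names(counts), counts)
  S <- length(groups)
  species_id <- sprintf("sp%04d", seq_len(S))

  # --- range centroids and widths -----------------------------------------
  cen <- with_seed(child_seed(config$seed, "centroids"), {
    list(row = 1 + sample_gradient_pos(S, config$gradient_strength) * (R - 1),
         col = runif(S, 0.5, C + 0.5))
  })
  area <- with_seed(child_seed(config$seed, "ranges"), {
    a <- rlnorm(S, config$range_size_lognormal[[1]],
                config$range_size_lognormal[[2]])
    pmin(pmax(a, 4), 0.5 * n)
  })
  sigma <- sqrt(area / (2 * pi))
  sigma <- pmin(sigma, min(R, C) / 3)

  suit_now <- matrix(0, n, S, dimnames = list(NULL, species_id))
  suit_fut <- matrix(0, n, S, dimnames = list(NULL, species_id))
  endemism <- numeric(S)
  fut_sigma <- sigma * config$future_width_mult
  for (j in seq_len(S)) {
    suit_now[, j] <- gaussian_bump(R, C, cen$row[j], cen$col[j], sigma[j])
    if (config$shift_cells == 0 && config$future_width_mult == 1) {
      suit_fut[, j] <- suit_now[, j]
    } else {
      suit_fut[, j] <- gaussian_bump(R, C, cen$row[j] + config$shift_cells,
                                     cen$col[j], fut_sigma[j])
    }
    in_grid <- sum(gaussian_bump(R, C, cen$row[j], cen$col[j], sigma[j],
                                 floor = 0))
    endemism[j] <- min(in_grid / bump_total_mass(cen$row[j], cen$col[j],
                                                 sigma[j]), 1)
  }

  # --- masks ----------------------------------------------------------------
  coverage <- with_seed(child_seed(config$seed, "coverage"),
                        clustered_coverage(R, C, config$protected_fraction,
                                           0.43, config$protected_bias))
  hfi <- with_seed(child_seed(config$seed, "hfi"), {
    f <- clustered_coverage(R, C, 0.4, 0.43, -1.5) # southern-biased pressure
    f <- f + 0.3 * southness(cell_row(seq_len(n), R), R)
    q <- stats::quantile(f, 0.95, type = 7, names = FALSE)
    f / q * 10 # ~5% of cells exceed the HFI threshold of 10
  })
  excluded <- with_seed(child_seed(config$seed, "excluded"), {
    if (config$excluded_fraction <= 0) integer(n) else {
      f <- clustered_coverage(R, C, config$excluded_fraction, 0.43, 0)
      as.integer(f >= 0.43)
    }
  })

  subpol <- with_seed(child_seed(config$seed, "subregions"),
                      voronoi_regions(R, C, config$n_subregions_political))
  subeco <- with_seed(child_seed(config$seed, "subregions") + 7L,
                      voronoi_regions(R, C, config$n_subregions_ecological,
                                      latitudinal = TRUE))

  # --- species metadata -----------------------------------------------------
  range_now <- colSums(suit_now)
  rarity <- 1 - (rank(range_now, ties.method = "average") - 0.5) / S
  status <- with_seed(child_seed(config$seed, "status"), {
    nat_risk <- runif(S) < (0.05 + 0.35 * rarity)
    glo_risk <- runif(S) < (0.02 + 0.20 * rarity)
    list(
      national = ifelse(nat_risk,
                        sample(c("special_concern", "threatened", "endangered"),
                               S, replace = TRUE),
                        "not_at_risk"),
      global = ifelse(glo_risk,
                      sample(c("vulnerable", "endangered", "critically_endangered"),
                             S, replace = TRUE),
                      "least_concern")
    )
  })
  species <- tibble::tibble(
    species_id = species_id,
    group = groups,
    kingdom = kingdom_of_group(groups),
    status_national = status$national,
    status_global = status$global,
    range_area = area,
    endemism_share = endemism
  )

  traits <- with_seed(child_seed(config$seed, "traits"), {
    lbs <- rnorm(S)
    tibble::tibble(
      species_id = species_id,
      kingdom = species$kingdom,
      body_size = lbs,
      reproductive_output = rnorm(S) - 0.4 * lbs,
      longevity = 0.6 * lbs + rnorm(S, sd = 0.8),
      resource_guild = sample(c("generalist", "specialist", "intermediate"),
                              S, replace = TRUE)
    )
  })

  tree <- with_seed(child_seed(config$seed, "tree"),
                    kingdom_tree(split(species_id, species$kingdom)))

  structure(
    list(grid = grid_def(R, C),
         suitability_current = suit_now,
         suitability_future = suit_fut,
         coverage = coverage, hfi = hfi, excluded = excluded,
         subregions_political = subpol, subregions_ecological = subeco,
         species = species, traits = traits, tree = tree,
         config = config),
    class = "landscape"
  )
}

# random coalescent tree per kingdom (rescaled to unit depth), grafted into
# one rooted binary tree by Newick splicing so kingdoms stay monophyletic
kingdom_tree <- function(tips_by_kingdom) {
  chunk <- vapply(tips_by_kingdom, function(tips) {
    if (length(tips) == 1) return(paste0(tips, ":1"))
    tr <- ape::rcoal(length(tips), tip.label = tips)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    paste0(sub(";$", "", ape::write.tree(tr)), ":0.5")
  }, character(1))
  nest <- chunk[length(chunk)]
  for (i in rev(seq_len(length(chunk) - 1))) {
    nest <- if (i == 1) {
      paste0("(", chunk[i], ",", nest, ");")
    } else {
      paste0("(", chunk[i], ",", nest, "):0.5")
    }
  }
  if (length(chunk) == 1) nest <- paste0("(", nest, ");")
  ape::read.tree(text = nest)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d grid, %d species (%s)\n",
              x$grid$nrow, x$grid$ncol, nrow(x$species),
              paste(sprintf("%s: %d", names(table(x$species$kingdom)),
                            as.integer(table(x$species$kingdom))),
                    collapse = ", ")))
  cat(sprintf("  protected cells (coverage >= 0.43): %.1f%%; excluded flag: %.1f%%\n",
              100 * mean(x$coverage >= 0.43), 100 * mean(x$excluded == 1)))
  invisible(x)
}

#' Sample biased species occurrence points
#'
#' Draws point records from a landscape's current suitability surfaces with a
#' configurable southward sampling bias (per-cell sampling probability
#' proportional to `suitability * exp(bias_strength * southness)`), emulating
#' the strong latitudinal observation bias of aggregated occurrence archives.
#' A fraction of points can be made erroneous (placed uniformly at random,
#' typically far outside the species' range) to exercise outlier filters.
#'
#' @param landscape A [generate_landscape()] result.
#' @param n_points Total number of points to draw (allocated across species
#'   proportionally to range size).
#' @param bias_strength Nonnegative southward bias; 0 samples proportionally
#'   to suitability alone. Defaults to the landscape config's value.
#' @param error_fraction Fraction of points placed uniformly at random.
#' @param seed Integer seed (defaults to the config's occurrence child seed).
#' @return A tibble with columns `x`, `y`, `species_id`, `erroneous`.
#' @export
generate_occurrences <- function(landscape, n_points = 2000,
                                 bias_strength = NULL, error_fraction = 0,
                                 seed = NULL) {
  stopifnot(inherits(landscape, "landscape"), n_points > 0,
            error_fraction >= 0, error_fraction <= 1)
  cfg <- landscape$config
  bias_strength <- bias_strength %||% cfg$sampling_bias_strength
  seed <- seed %||% child_seed(cfg$seed, "occurrences")
  grid <- landscape$grid
  n <- n_cells(grid)
  suit <- landscape$suitability_current
  S <- ncol(suit)
  south <- southness(cell_row(seq_len(n), grid$nrow), grid$nrow)
  bias <- exp(bias_strength * south)

  with_seed(seed, {
    range_sz <- colSums(suit)
    per_sp <- as.vector(stats::rmultinom(1, n_points, prob = range_sz))
    pieces <- lapply(seq_len(S), function(j) {
      m <- per_sp[j]
      if (m == 0) return(NULL)
      n_err <- stats::rbinom(1, m, error_fraction)
      n_ok <- m - n_err
      cells <- integer(0)
      if (n_ok > 0) {
        p <- suit[, j] * bias
        cells <- sample.int(n, n_ok, replace = TRUE, prob = p)
      }
      err_cells <- if (n_err > 0) sample.int(n, n_err, replace = TRUE) else integer(0)
      all_cells <- c(cells, err_cells)
      ctr <- cell_center_xy(grid, all_cells)
      tibble::tibble(
        x = ctr$x + runif(length(all_cells), -0.5, 0.5) * grid$cell_size,
        y = ctr$y + runif(length(all_cells), -0.5, 0.5) * grid$cell_size,
        species_id = colnames(suit)[j],
        erroneous = rep(c(FALSE, TRUE), c(n_ok, n_err))
      )
    })
    dplyr::bind_rows(pieces)
  })
}
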