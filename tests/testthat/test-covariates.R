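# Confounder computation: slope, distances, grid path distance, buffers.

test_that("slope is zero on a flat DEM and 45 degrees on a unit-gradient plane", {
  expect_equal(slope_from_dem(matrix(7, 6, 6), 30), matrix(0, 6, 6))
  plane <- outer(rep(0, 6), (0:5) * 30, "+")   # rises 30 m per 30 m east
  s <- slope_from_dem(plane, 30)
  expect_equal(s[2:5, 2:5], matrix(45, 4, 4), tolerance = 1e-10)
  expect_error(slope_from_dem(matrix(1, 1, 1), 30), "at least 2x2")
})

test_that("slope of a symmetric ridge is symmetric about the ridge line", {
  ridge <- outer(rep(1, 7), -abs(-3:3) * 10)
  s <- slope_from_dem(ridge, 30)
  expect_equal(s[, 1:3], s[, 7:5])
})

test_that("euclidean distance handles points, segments and minima", {
  feats <- list(points = data.frame(x = c(0, 0), y = c(100, 400)))
  expect_equal(euclidean_distance(0, 0, feats), 100)
  road <- list(segments = data.frame(x1 = 0, y1 = 50, x2 = 300, y2 = 50))
  expect_equal(euclidean_distance(150, 50, road), 0)
  expect_equal(euclidean_distance(150, 200, road), 150)
  expect_error(euclidean_distance(0, 0, list()), "empty")
})

test_that("a single road along one column gives distances in cell_size steps", {
  cs <- 30
  # vertical line through the centers of column 2 (0-based) on a 5x5 grid
  road <- list(segments = data.frame(x1 = 2.5 * cs, y1 = -1e6,
                                     x2 = 2.5 * cs, y2 = 1e6))
  d <- feature_distance_raster(5, 5, cs, road)
  for (col in 0:4) expect_equal(d[, col + 1], rep(abs(col - 2) * cs, 5))
})

test_that("grid distance to nonforest matches hand geometry", {
  f <- matrix(TRUE, 3, 3); f[1, 1] <- FALSE
  # opposite corner: two diagonal steps
  expect_equal(grid_distance_to_nonforest(f, 2, 2, 30), 2 * 30 * sqrt(2))
  # orthogonal neighbor: one step
  f2 <- matrix(TRUE, 3, 3); f2[1, 2] <- FALSE
  expect_equal(grid_distance_to_nonforest(f2, 0, 0, 30), 30)
  # nonforest sample gets 0
  expect_equal(grid_distance_to_nonforest(f, 0, 0, 30), 0)
  # all-forest layer: sentinel with warning
  expect_warning(d <- grid_distance_transform(matrix(TRUE, 4, 5), 30),
                 "sentinel")
  expect_true(all(d == (4 + 5) * 30))
})

test_that("grid distance equals a Dijkstra oracle on random small grids", {
  set.seed(421)
  for (rep in 1:40) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    f <- matrix(runif(nr * nc) < 0.7, nr, nc)
    if (!any(!f)) f[sample(nr * nc, 1)] <- FALSE
    dt <- grid_distance_transform(f, 30)
    r0 <- sample(0:(nr - 1), 1); c0 <- sample(0:(nc - 1), 1)
    expect_equal(dt[r0 + 1, c0 + 1],
                 dijkstra_grid_distance(f, r0, c0, 30), tolerance = 1e-9)
  }
})

test_that("euclidean distance lower-bounds the grid path distance", {
  set.seed(99)
  for (rep in 1:10) {
    f <- matrix(runif(49) < 0.8, 7, 7)
    if (!any(!f)) f[25] <- FALSE
    dt <- grid_distance_transform(f, 30)
    nf <- which(!f, arr.ind = TRUE)
    feats <- list(points = data.frame(x = (nf[, 2] - 0.5) * 30,
                                      y = (nf[, 1] - 0.5) * 30))
    for (r in 1:7) for (c in 1:7) {
      eu <- euclidean_distance((c - 0.5) * 30, (r - 0.5) * 30, feats)
      expect_gte(dt[r, c] + 1e-9, eu)
    }
  }
})

test_that("the 126 m buffer on a 30 m grid holds exactly 57 pixel centers", {
  # independent lattice enumeration
  n <- 0L
  for (dx in -5:5) for (dy in -5:5)
    if (30 * sqrt(dx^2 + dy^2) <= 126) n <- n + 1L
  expect_equal(n, 57L)
  f <- matrix(TRUE, 11, 11)
  expect_equal(buffer_forest_proportion(f, 5, 5, 30, radius = 126), 1.0)
  f[1, 1] <- FALSE   # outside the buffer of the center pixel
  expect_equal(buffer_forest_proportion(f, 5, 5, 30, radius = 126), 1.0)
  f2 <- matrix(TRUE, 11, 11); f2[5, 5] <- FALSE  # inside (adjacent to center)
  expect_equal(buffer_forest_proportion(f2, 5, 5, 30, radius = 126), 56 / 57)
  expect_equal(buffer_forest_proportion(matrix(FALSE, 11, 11), 5, 5, 30), 0)
  expect_error(buffer_forest_proportion(f, 0, 0, 30), "beyond the raster")
})

test_that("buffer raster agrees with the per-point computation", {
  set.seed(5)
  f <- matrix(runif(400) < 0.6, 20, 20)
  br <- buffer_forest_raster(f, 30, radius = 126)
  for (i in 1:20) {
    r <- sample(4:15, 1); c <- sample(4:15, 1)
    expect_equal(br[r + 1, c + 1], buffer_forest_proportion(f, r, c, 30))
  }
  expect_true(all(is.na(br[1:4, ])))
})

test_that("assembled covariates equal the individually computed operations", {
  land <- simulate_landscape(tiny_scenario(seed = 33))
  panel <- land$panel; surf <- land$surfaces
  s <- draw_samples(eligible_pixels(panel, land$zones), 0.02, seed = 1)
  s <- filter_border_buffers(s, grid_boundary(panel))
  yr <- 2008
  cov <- assemble_covariates(s, surf, panel, yr)
  yi <- match(yr, panel$years)
  i <- which.max(s$sample_id)
  r <- s$row[i]; c <- s$col[i]
  expect_equal(cov$elevation[i], surf$elevation[r + 1, c + 1])
  expect_equal(cov$slope[i], surf$slope[r + 1, c + 1])
  expect_equal(cov$dist_road[i],
               euclidean_distance(s$x[i], s$y[i],
                                  list(segments = surf$features$roads)))
  expect_equal(cov$dist_village[i],
               euclidean_distance(s$x[i], s$y[i],
                                  list(points = surf$features$villages)))
  expect_equal(cov$forest_at_est[i], as.numeric(panel$forest[r + 1, c + 1, yi]))
  expect_equal(cov$tcc_at_est[i], as.numeric(panel$tcc[r + 1, c + 1, yi]))
  expect_equal(cov$dist_nonforest_at_est[i],
               grid_distance_to_nonforest(panel$forest[, , yi], r, c, 30))
  expect_equal(cov$forest_prop_buffer_at_est[i],
               buffer_forest_proportion(panel$forest[, , yi], r, c, 30))
  # boundary reference years work; out-of-range errors
  expect_silent(assemble_covariates(s, surf, panel, min(panel$years)))
  expect_error(assemble_covariates(s, surf, panel, 1970), "outside panel years")
})
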