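# Synthetic landscape generator: determinism, dynamics, placement, injection.

test_that("scenario_config validates its invariants", {
  expect_error(scenario_config(grid_rows = 16), "must be >= 32")
  expect_error(scenario_config(years = 2000:2010), ">= 18 years")
  expect_error(scenario_config(cell_size = 0), "cell_size")
  expect_error(scenario_config(noise_sd = -1), "noise_sd")
  expect_error(scenario_config(establishment_years = 1950:1960), "within the years span")
  expect_error(scenario_config(hazard_reduction = 2), "hazard_reduction")
})

test_that("identical config and seed give byte-identical landscapes", {
  cfg <- tiny_scenario(seed = 31)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$surfaces$elevation, b$surfaces$elevation)
  expect_identical(a$panel$tcc, b$panel$tcc)
  expect_identical(a$zones$zone_id, b$zones$zone_id)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("panel respects value invariants", {
  land <- simulate_landscape(tiny_scenario(seed = 5))
  expect_true(all(land$panel$tcc >= 0 & land$panel$tcc <= 100))
  expect_true(all(land$panel$forest %in% c(TRUE, FALSE)))
  excl <- Reduce(`|`, land$zones$exclusions)
  expect_false(any(land$zones$zone_id > 0 & excl))
  # forest state is derived from land cover
  expect_identical(land$panel$forest, land$panel$landcover <= 2L)
})

test_that("zero trend, noise and clearing give a constant TCC trajectory", {
  cfg <- tiny_scenario(seed = 2, baseline_tcc_trend = 0, noise_sd = 0,
                       deforestation_base_rate = 0)
  surf <- generate_surfaces(cfg)
  panel <- simulate_panel(cfg, surf)
  expect_equal(panel$tcc[, , 1], panel$tcc[, , length(cfg$years)])
})

test_that("noiseless declining trend follows the closed-form drift", {
  cfg <- tiny_scenario(seed = 3, baseline_tcc_trend = -0.5, noise_sd = 0,
                       deforestation_base_rate = 0)
  surf <- generate_surfaces(cfg)
  panel <- simulate_panel(cfg, surf)
  ny <- length(cfg$years)                      # 19 years -> 18 steps
  drop_total <- 0.5 * (ny - 1)
  # forest pixels clear of the canopy floor decline exactly linearly
  sel <- panel$forest[, , 1] & panel$tcc[, , 1] >= cfg$canopy_floor + drop_total
  expect_gt(sum(sel), 100)
  d <- panel$tcc[, , 1][sel] - panel$tcc[, , ny][sel]
  expect_equal(d, rep(drop_total, sum(sel)), tolerance = 1e-12)
  # a middle year sits on the line
  mid <- panel$tcc[, , 10][sel]
  expect_equal(panel$tcc[, , 1][sel] - mid, rep(0.5 * 9, sum(sel)),
               tolerance = 1e-12)
  # nonforest land holds a stationary residual cover
  nf <- !panel$forest[, , 1]
  expect_equal(panel$tcc[, , 1][nf], panel$tcc[, , ny][nf], tolerance = 1e-12)
})

test_that("landscape-mean TCC with a negative trend has Mann-Kendall S < 0", {
  cfg <- scenario_config(grid_rows = 48, grid_cols = 48, years = 1989:2019,
                         n_zones = 0, baseline_tcc_trend = -0.5,
                         noise_sd = 2, seed = 4)
  surf <- generate_surfaces(cfg)
  panel <- simulate_panel(cfg, surf)
  mk <- mann_kendall(landscape_mean_tcc(panel))
  expect_lt(mk$S, 0)
})

test_that("unbiased placement is uniform over eligible pixels (chi-square GOF)", {
  seeds_rc <- matrix(NA_integer_, 500, 2)
  for (i in 1:500) {
    cfg <- scenario_config(grid_rows = 32, grid_cols = 32, years = 2000:2017,
                           n_zones = 1, establishment_years = 2008,
                           zone_area_px = 1, n_exclusions = 0, seed = 1000 + i)
    surf <- generate_surfaces(cfg)
    panel <- simulate_panel(cfg, surf)
    z <- place_zones(cfg, surf, panel)
    seeds_rc[i, ] <- c(z$zones$zones$seed_row, z$zones$zones$seed_col)
  }
  # 2x2 quadrants, equal expected counts
  bin <- (seeds_rc[, 1] >= 16) * 2 + (seeds_rc[, 2] >= 16) + 1
  gof <- chisq.test(tabulate(bin, 4), p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.01)
})

test_that("a strong positive elevation coefficient pulls zones uphill", {
  diffs <- vapply(1:5, function(i) {
    cfg <- tiny_scenario(seed = 50 + i,
                         placement_bias_coefs = c(2, 0, 0, 0, 0))
    surf <- generate_surfaces(cfg)
    panel <- simulate_panel(cfg, surf)
    z <- place_zones(cfg, surf, panel)
    inz <- z$zones$zone_id > 0
    mean(surf$elevation[inz]) - mean(surf$elevation[!inz])
  }, 0)
  expect_true(all(diffs > 0))
})

test_that("n_zones = 0 gives an empty zone set and an unchanged panel", {
  cfg <- tiny_scenario(seed = 9, n_zones = 0)
  surf <- generate_surfaces(cfg)
  panel <- simulate_panel(cfg, surf)
  z <- place_zones(cfg, surf, panel)
  expect_equal(nrow(z$zones$zones), 0)
  expect_true(all(z$zones$zone_id == 0L))
  injected <- inject_effect(panel, z$zones, z$ground_truth)
  expect_equal(injected$tcc, panel$tcc)
})

test_that("null effects leave the panel identical", {
  cfg <- tiny_scenario(seed = 10, effect_level = 0, effect_trend = 0,
                       hazard_reduction = 0)
  land <- simulate_landscape(cfg)
  surf <- generate_surfaces(cfg)
  base <- simulate_panel(cfg, surf)
  expect_equal(land$panel$tcc, base$tcc)
  expect_equal(land$panel$forest, base$forest)
})

test_that("injected effect matches the level + trend * elapsed formula", {
  cfg <- tiny_scenario(seed = 11, noise_sd = 0, deforestation_base_rate = 0,
                       effect_level = 2, effect_trend = 0.5,
                       hazard_reduction = 0)
  surf <- generate_surfaces(cfg)
  base <- simulate_panel(cfg, surf)
  pz <- place_zones(cfg, surf, base)
  treated <- inject_effect(base, pz$zones, pz$ground_truth)
  g <- pz$ground_truth[1, ]
  px <- which(pz$zones$zone_id == g$zone_id)
  yi4 <- match(g$est_year + 4, cfg$years)
  yi0 <- match(g$est_year, cfg$years)
  gap4 <- treated$tcc[, , yi4][px] - base$tcc[, , yi4][px]
  expect_equal(gap4, rep(2 + 0.5 * 4, length(px)), tolerance = 1e-10)
  # establishment year itself is unmodified (coded pre-intervention)
  expect_equal(treated$tcc[, , yi0][px], base$tcc[, , yi0][px])
})

test_that("negative cohort slope makes later cohorts strictly less effective", {
  cfg <- tiny_scenario(seed = 12, cohort_effect_slope = -0.05)
  surf <- generate_surfaces(cfg)
  panel <- simulate_panel(cfg, surf)
  gt <- place_zones(cfg, surf, panel)$ground_truth
  gt <- gt[order(gt$est_year), ]
  expect_true(all(diff(unique(gt$level_effect[order(gt$est_year)])) < 0 |
                    length(unique(gt$est_year)) < 2))
  d_est <- gt$est_year - min(gt$est_year)
  expect_equal(gt$level_effect, cfg$effect_level - 0.05 * d_est)
  expect_equal(gt$trend_effect, cfg$effect_trend - 0.05 * d_est)
  # every ground-truth zone exists in the emitted zone set
  expect_true(all(gt$zone_id %in% unique(as.vector(
    place_zones(cfg, surf, panel)$zones$zone_id))))
})
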