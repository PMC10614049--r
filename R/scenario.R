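#' Scenario configuration for the synthetic landscape generator
#'
#' Bundles every knob of the synthetic landscape: grid geometry, calendar
#' span, zone (community-forest) placement, baseline canopy dynamics and the
#' injected treatment effects whose recovery the inference chain is validated
#' against.
#'
#' @param grid_rows,grid_cols Pixel counts (each at least 32).
#' @param cell_size Pixel edge length in meters (default 30, Landsat scale).
#' @param years Inclusive calendar span, e.g. `1989:2019`; at least 18 years
#'   so a pooled event window of -8..+9 is attainable.
#' @param n_zones Number of community-forest zones to place.
#' @param establishment_years Calendar years zones may be established in;
#'   defaults to 1994-2010 with no zone in 1996, mirroring the Cambodian CF
#'   register the analysis design is patterned on.
#' @param zone_area_px Target zone patch area in pixels (default 210, i.e.
#'   ~19 ha at 30 m — scaled down from real community-forest sizes so that
#'   dozens of zones plus an ample control reservoir fit on a desk-scale
#'   grid).
#' @param baseline_tcc_trend Baseline drift of FOREST canopy cover,
#'   percentage points per year (negative = secular degradation). Nonforest
#'   land keeps a stationary residual cover.
#' @param effect_level Level effect injected the year after establishment,
#'   TCC percentage points (the beta2 ground truth).
#' @param effect_trend Additional trend effect, percentage points per year
#'   since establishment (the beta3 ground truth).
#' @param cohort_effect_slope Change in BOTH injected effects per calendar
#'   year of establishment (0 = all cohorts equal; negative = later cohorts
#'   less effective). Cohort c receives
#'   `effect_level + cohort_effect_slope * (est_year - min(est_year))` as its
#'   level effect, and analogously for the trend effect.
#' @param hazard_reduction Proportional reduction of the forest-clearing
#'   hazard inside zones after establishment, in `[0, 1]`.
#' @param placement_bias_coefs Named or length-5 numeric vector of logistic
#'   coefficients tying zone seed placement to the standardized static
#'   covariates (elevation, slope, dist_road, dist_village, dist_district).
#'   Zeros give uniform placement over eligible pixels.
#' @param noise_sd SD of the iid per-pixel, per-year TCC observation noise
#'   (percentage points).
#' @param deforestation_base_rate Baseline probability per year that a forest
#'   pixel of median accessibility is cleared.
#' @param forest_tcc_threshold Initial canopy cover above which a pixel
#'   starts as forest.
#' @param canopy_floor Minimum latent canopy cover (%) on nonforest and
#'   cleared land: agricultural mosaics and shrubland retain scattered
#'   trees, so the latent TCC never drifts below this level. Keeping the
#'   floor a couple of noise SDs above 0 also keeps the observed-TCC
#'   censoring at 0 rare, so injected effects stay additive in expectation.
#' @param corr_range Spatial autocorrelation range of the latent fields, in
#'   meters (Gaussian smoothing scale).
#' @param n_roads,n_villages,n_districts Counts of synthetic access features.
#' @param n_exclusions Number of exclusion patches (water / protected area /
#'   concession), cycled over the three types.
#' @param exclusion_area_px Target area per exclusion patch, pixels.
#' @param seed Integer seed; the whole scenario is a deterministic function
#'   of the configuration including this seed.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @examples
#' cfg <- scenario_config(grid_rows = 64, grid_cols = 64, n_zones = 6,
#'                        establishment_years = 2000:2005, seed = 1)
#' cfg$effect_level
#' @export
scenario_config <- function(grid_rows = 200, grid_cols = 200, cell_size = 30,
                            years = 1989:2019, n_zones = 40,
                            establishment_years = setdiff(1994:2010, 1996),
                            zone_area_px = 210,
                            baseline_tcc_trend = -0.5,
                            effect_level = 2.0, effect_trend = 0.5,
                            cohort_effect_slope = 0,
                            hazard_reduction = 0.5,
                            placement_bias_coefs = c(elevation = 0, slope = 0,
                                                     dist_road = 0,
                                                     dist_village = 0,
                                                     dist_district = 0),
                            noise_sd = 5,
                            deforestation_base_rate = 0.001,
                            forest_tcc_threshold = 40,
                            canopy_floor = 8,
                            corr_range = 600,
                            n_roads = 3, n_villages = 25, n_districts = 3,
                            n_exclusions = 3, exclusion_area_px = 60,
                            seed = 1L) {
  years <- sort(as.integer(years))
  if (grid_rows < 32 || grid_cols < 32)
    stopf("grid dimensions must be >= 32 (got %d x %d)", grid_rows, grid_cols)
  if (cell_size <= 0) stopf("cell_size must be > 0")
  if (length(years) < 18)
    stopf("years span must cover >= 18 years (got %d)", length(years))
  if (any(diff(years) != 1L)) stopf("years must be consecutive")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (n_zones < 0) stopf("n_zones must be >= 0")
  if (n_zones > 0 &&
      (any(establishment_years < min(years)) ||
       any(establishment_years > max(years))))
    stopf("establishment_years must lie within the years span")
  if (hazard_reduction < 0 || hazard_reduction > 1)
    stopf("hazard_reduction must be in [0, 1]")
  if (deforestation_base_rate < 0 || deforestation_base_rate > 1)
    stopf("deforestation_base_rate must be a probability")
  if (length(placement_bias_coefs) != 5)
    stopf("placement_bias_coefs must have length 5")

  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size, years = years,
              n_zones = as.integer(n_zones),
              establishment_years = sort(unique(as.integer(establishment_years))),
              zone_area_px = as.integer(zone_area_px),
              baseline_tcc_trend = baseline_tcc_trend,
              effect_level = effect_level, effect_trend = effect_trend,
              cohort_effect_slope = cohort_effect_slope,
              hazard_reduction = hazard_reduction,
              placement_bias_coefs = placement_bias_coefs,
              noise_sd = noise_sd,
              deforestation_base_rate = deforestation_base_rate,
              forest_tcc_threshold = forest_tcc_threshold,
              canopy_floor = canopy_floor,
              corr_range = corr_range,
              n_roads = as.integer(n_roads),
              n_villages = as.integer(n_villages),
              n_districts = as.integer(n_districts),
              n_exclusions = as.integer(n_exclusions),
              exclusion_area_px = as.integer(exclusion_area_px),
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d x %d grid @ %gm, %d-%d, %d zones (%d cohort years)\n",
              x$grid_rows, x$grid_cols, x$cell_size, min(x$years), max(x$years),
              x$n_zones, length(x$establishment_years)))
  cat(sprintf("  baseline trend %+g %%/yr, effects: level %g, trend %g, cohort slope %g\n",
              x$baseline_tcc_trend, x$effect_level, x$effect_trend,
              x$cohort_effect_slope))
  cat(sprintf("  noise sd %g, clearing base rate %g/yr, hazard reduction %g, seed %d\n",
              x$noise_sd, x$deforestation_base_rate, x$hazard_reduction, x$seed))
  invisible(x)
}
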