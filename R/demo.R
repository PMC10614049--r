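#' Benchmark validation scenario
#'
#' The desk-scale study scenario used by the package's validation
#' experiments: a 200 x 200 pixel landscape (30 m cells, 6 x 6 km) observed
#' 1989-2019, 40 community-forest zones established 1997-2010,
#' confounder-biased placement (zones uphill and near roads), TCC
#' observation noise of 5 percentage points, and injectable treatment
#' effects. Placement bias coefficients (+0.4 elevation, -0.4 road
#' distance) are strong enough that the pre-matching pooled imbalance is far
#' above the 0.25 acceptability bound while common support remains. The
#' clearing-hazard treatment channel is off by default here so that the
#' injected `(level, trend)` pair is the exact linear ground truth for the
#' interrupted time-series estimates.
#'
#' @param seed Integer seed.
#' @param effect_level,effect_trend Injected level (TCC points) and trend
#'   (points/yr) effects; defaults 2.0 and 0.5.
#' @param cohort_effect_slope Change of both effects per establishment year.
#' @param ... Further overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
study_scenario <- function(seed, effect_level = 2.0, effect_trend = 0.5,
                           cohort_effect_slope = 0, ...) {
  args <- utils::modifyList(
    list(grid_rows = 200, grid_cols = 200, years = 1989:2019,
         n_zones = 40, establishment_years = 1997:2010,
         effect_level = effect_level, effect_trend = effect_trend,
         cohort_effect_slope = cohort_effect_slope,
         hazard_reduction = 0,
         placement_bias_coefs = c(elevation = 0.4, slope = 0,
                                  dist_road = -0.4, dist_village = 0,
                                  dist_district = 0),
         noise_sd = 5, seed = seed),
    list(...))
  do.call(scenario_config, args)
}
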