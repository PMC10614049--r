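# Injection of known treatment effects into a simulated panel.

#' Inject ground-truth treatment effects into a panel
#'
#' For every pixel inside a zone with establishment year `y`, and every
#' calendar year strictly after `y`, adds the cohort's level effect plus its
#' trend effect times the years elapsed since establishment to the latent
#' (pre-clipping) TCC. The establishment year itself is left unmodified, so
#' event time 0 is pre-intervention, matching the ITS design coding. In
#' addition the forest-clearing hazard inside zones is multiplied by
#' `1 - hazard_reduction` for post-establishment years, and the clearing
#' process is re-realized against the SAME underlying uniform draws, so the
#' treated panel is a coupled counterfactual of the untreated one (a pixel
#' cleared under treatment is always cleared without it).
#'
#' @param panel A `landscape_panel` from [simulate_panel()].
#' @param zones A `zone_set` from [place_zones()].
#' @param ground_truth Ground-truth data frame from [place_zones()]
#'   (`zone_id`, `est_year`, `level_effect`, `trend_effect`,
#'   `hazard_reduction`).
#' @return A new `landscape_panel` with effects applied (`$injected` is
#'   `TRUE`, `$ground_truth` attached).
#' @export
inject_effect <- function(panel, zones, ground_truth) {
  stopifnot(inherits(panel, "landscape_panel"), inherits(zones, "zone_set"))
  if (zones$rows != panel$rows || zones$cols != panel$cols)
    stopf("zone raster (%dx%d) does not match panel grid (%dx%d)",
          zones$rows, zones$cols, panel$rows, panel$cols)
  if (nrow(ground_truth) > 0 &&
      !all(ground_truth$zone_id %in% zones$zones$zone_id))
    stopf("ground truth references zone ids missing from the zone set")
  ny <- length(panel$years)
  nr <- panel$rows; nc <- panel$cols

  effect <- array(0, c(nr, nc, ny))
  hazard_mult <- NULL
  for (i in seq_len(nrow(ground_truth))) {
    g <- ground_truth[i, ]
    px <- which(zones$zone_id == g$zone_id)
    if (length(px) == 0) next
    post <- which(panel$years > g$est_year)
    for (yi in post) {
      dt <- panel$years[yi] - g$est_year
      effect[px + (yi - 1L) * nr * nc] <-
        g$level_effect + g$trend_effect * dt
    }
    if (g$hazard_reduction > 0) {
      if (is.null(hazard_mult)) hazard_mult <- array(1, c(nr, nc, ny))
      for (yi in post)
        hazard_mult[px + (yi - 1L) * nr * nc] <- 1 - g$hazard_reduction
    }
  }

  state <- panel[c("years", "rows", "cols", "cell_size", "trend", "floor",
                   "L0", "eps", "hazard", "clear_u", "drop_frac",
                   "init_landcover", "conv_class")]
  conv_year <- first_clearing_year(state, hazard_mult = hazard_mult)
  realize_panel(state, conv_year = conv_year, effect = effect,
                meta = list(injected = TRUE, ground_truth = ground_truth))
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper chaining [generate_surfaces()], [simulate_panel()],
#' [place_zones()] and [inject_effect()] for one scenario.
#'
#' @param config A [scenario_config()].
#' @return List with `surfaces`, `panel` (effects injected), `zones`,
#'   `ground_truth` and the `config`.
#' @export
simulate_landscape <- function(config) {
  surfaces <- generate_surfaces(config)
  panel0 <- simulate_panel(config, surfaces)
  pz <- place_zones(config, surfaces, panel0)
  panel <- inject_effect(panel0, pz$zones, pz$ground_truth)
  list(surfaces = surfaces, panel = panel, zones = pz$zones,
       ground_truth = pz$ground_truth, config = config)
}
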