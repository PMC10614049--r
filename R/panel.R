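# Annual TCC / land-cover panel simulation.
#
# The panel keeps its full generative state (latent initial canopy, drift,
# observation noise draws, clearing hazards and uniforms) so that treatment
# effects can later be injected by re-realizing the same draws under modified
# dynamics: treated and counterfactual trajectories share every random draw.

LANDCOVER_LEVELS <- c("natural_forest", "plantation_forest", "agriculture",
                      "grass_shrub", "urban_water")

#' Simulate the annual landscape panel
#'
#' Generates a multi-decade panel of per-pixel tree canopy cover (TCC, %),
#' land-cover class and binary forest state on the scenario grid:
#'
#' * initial TCC is a spatially autocorrelated field, positively associated
#'   with elevation (this is what makes biased zone placement confounding);
#' * each year the latent TCC of FOREST pixels drifts by
#'   `baseline_tcc_trend` (secular degradation); nonforest and cleared land
#'   holds a stationary residual cover, never below `canopy_floor`.
#'   Observed TCC adds iid `N(0, noise_sd^2)` observation error and is
#'   clipped to `[0, 100]`;
#' * forest pixels are cleared with a per-pixel annual hazard increasing
#'   with accessibility (near roads, low elevation); a cleared pixel drops
#'   most of its canopy and its land cover converts to agriculture or
#'   grass/shrub;
#' * forest state is derived from land cover (natural + plantation forest).
#'
#' @param config A [scenario_config()].
#' @param surfaces Output of [generate_surfaces()] for the same config.
#' @return A `landscape_panel` object with arrays `tcc`, `forest`,
#'   `landcover` of dim `rows x cols x n_years` plus generative state.
#' @export
simulate_panel <- function(config, surfaces) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  ny <- length(config$years)
  with_seed(child_seed(config$seed, 2), {
    # latent initial canopy, tied to elevation
    zelev <- (surfaces$elevation - mean(surfaces$elevation)) /
      sd(surfaces$elevation)
    L0 <- 55 + 8 * zelev +
      12 * gaussian_field(nr, nc, config$corr_range / config$cell_size)
    L0 <- clip(L0, 2, 95)

    init_forest <- L0 >= config$forest_tcc_threshold
    init_landcover <- matrix(0L, nr, nc)
    u_cls <- matrix(runif(nr * nc), nr, nc)
    init_landcover[init_forest] <- ifelse(u_cls[init_forest] < 0.1, 2L, 1L)
    nf <- !init_forest
    init_landcover[nf] <- ifelse(u_cls[nf] < 0.6, 3L,
                                 ifelse(u_cls[nf] < 0.95, 4L, 5L))
    # nonforest pixels start with low canopy (above the residual floor)
    L0[nf] <- pmin(L0[nf],
                   runif(sum(nf), config$canopy_floor,
                         max(config$forest_tcc_threshold / 2,
                             config$canopy_floor + 2)))

    # clearing hazard rises with accessibility
    za <- scale(-log1p(as.vector(surfaces$dist_road)))[, 1] +
      0.5 * scale(-as.vector(surfaces$elevation))[, 1]
    za <- matrix(scale(za)[, 1], nr, nc)
    hazard <- clip(config$deforestation_base_rate * exp(0.7 * za), 0, 0.9)

    eps <- array(rnorm(nr * nc * ny, sd = config$noise_sd), c(nr, nc, ny))
    clear_u <- array(runif(nr * nc * ny), c(nr, nc, ny))
    drop_frac <- matrix(runif(nr * nc, 0.75, 0.95), nr, nc)
    conv_class <- matrix(ifelse(runif(nr * nc) < 0.7, 3L, 4L), nr, nc)

    state <- list(years = config$years, rows = nr, cols = nc,
                  cell_size = config$cell_size,
                  trend = config$baseline_tcc_trend,
                  floor = config$canopy_floor,
                  L0 = L0, eps = eps, hazard = hazard, clear_u = clear_u,
                  drop_frac = drop_frac, init_landcover = init_landcover,
                  conv_class = conv_class)
    conv_year <- first_clearing_year(state, hazard_mult = NULL)
    realize_panel(state, conv_year = conv_year, effect = NULL)
  })
}

# First-passage clearing year per pixel (NA = never cleared). hazard_mult is
# an optional rows x cols x ny array of multipliers (protection inside zones).
first_clearing_year <- function(state, hazard_mult = NULL) {
  ny <- length(state$years)
  conv <- matrix(NA_integer_, state$rows, state$cols)
  active <- state$init_landcover <= 2L   # still forest
  for (yi in 2:ny) {
    h <- state$hazard
    if (!is.null(hazard_mult)) h <- h * hazard_mult[, , yi]
    newly <- active & (state$clear_u[, , yi] < h)
    conv[newly] <- yi
    active <- active & !newly
  }
  conv
}

# Build the observed panel arrays from the generative state.
realize_panel <- function(state, conv_year, effect = NULL, meta = list()) {
  nr <- state$rows; nc <- state$cols; ny <- length(state$years)
  tcc <- array(0, c(nr, nc, ny))
  landcover <- array(0L, c(nr, nc, ny))
  has_conv <- !is.na(conv_year)
  # residual canopy left standing after clearing: (1 - drop) of the latent
  # level in the clearing year, held constant thereafter
  Uconv_resid <- matrix(0, nr, nc)
  if (any(has_conv)) {
    Uc <- state$L0[has_conv] + state$trend * (conv_year[has_conv] - 1)
    Uconv_resid[has_conv] <- (1 - state$drop_frac[has_conv]) * pmax(Uc, 0)
  }
  floor_ <- if (is.null(state$floor)) 0 else state$floor
  init_forest <- state$init_landcover <= 2L
  for (yi in seq_len(ny)) {
    # secular degradation drifts the canopy of FOREST land only: nonforest
    # mosaics hold a stationary residual cover, and a cleared pixel keeps
    # the (constant) residual left after the clearing drop. Latent
    # trajectories are therefore linear between events, and injected
    # effects (added on top, before clipping) stay additive.
    U <- state$L0 + ifelse(init_forest, state$trend * (yi - 1), 0)
    cleared <- has_conv & conv_year <= yi
    lat <- pmax(ifelse(cleared, Uconv_resid, U), floor_)
    if (!is.null(effect)) lat <- lat + effect[, , yi]
    tcc[, , yi] <- clip(lat + state$eps[, , yi], 0, 100)
    lc <- state$init_landcover
    lc[cleared] <- state$conv_class[cleared]
    landcover[, , yi] <- lc
  }
  forest <- landcover <= 2L
  dimnames(tcc) <- dimnames(landcover) <- dimnames(forest) <-
    list(NULL, NULL, state$years)
  out <- c(state,
           list(tcc = tcc, forest = forest, landcover = landcover,
                conv_year = conv_year,
                landcover_levels = LANDCOVER_LEVELS),
           meta)
  class(out) <- "landscape_panel"
  out
}

#' @export
print.landscape_panel <- function(x, ...) {
  ny <- length(x$years)
  cat(sprintf("<landscape_panel> %d x %d px @ %gm, %d-%d (%d years)\n",
              x$rows, x$cols, x$cell_size, min(x$years), max(x$years), ny))
  cat(sprintf("  mean TCC %.1f%% (first year) -> %.1f%% (last year); forest share %.2f -> %.2f\n",
              mean(x$tcc[, , 1]), mean(x$tcc[, , ny]),
              mean(x$forest[, , 1]), mean(x$forest[, , ny])))
  if (!is.null(x$injected) && isTRUE(x$injected))
    cat("  treatment effects injected\n")
  invisible(x)
}

#' Landscape-mean TCC series
#'
#' Mean observed TCC over all pixels for each panel year; handy for trend
#' screens of the simulated landscape.
#' @param panel A `landscape_panel`.
#' @return Named numeric vector (names = calendar years).
#' @export
landscape_mean_tcc <- function(panel) {
  setNames(apply(panel$tcc, 3, mean), panel$years)
}
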