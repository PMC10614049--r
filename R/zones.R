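# Community-forest zone placement with confounder-biased site selection,
# plus exclusion masks (water / protected areas / concessions).

neighbors8 <- function(px, nr, nc) {
  r <- ((px - 1L) %% nr) + 1L
  c <- ((px - 1L) %/% nr) + 1L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  rr <- r + dr; cc <- c + dc
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  (cc[ok] - 1L) * nr + rr[ok]
}

# Region-grow a contiguous patch from seed_px over available pixels.
grow_patch <- function(seed_px, target_area, available, nr, nc) {
  patch <- integer(0)
  frontier <- seed_px
  in_frontier <- logical(nr * nc)
  in_frontier[seed_px] <- TRUE
  while (length(patch) < target_area && length(frontier) > 0) {
    i <- if (length(frontier) == 1L) 1L else sample.int(length(frontier), 1L)
    px <- frontier[i]
    frontier <- frontier[-i]
    if (!available[px]) next
    patch <- c(patch, px)
    available[px] <- FALSE
    nb <- neighbors8(px, nr, nc)
    nb <- nb[available[nb] & !in_frontier[nb]]
    in_frontier[nb] <- TRUE
    frontier <- c(frontier, nb)
  }
  patch
}

#' Place community-forest zones with confounder-biased site selection
#'
#' Draws zone seed pixels with probability proportional to
#' `plogis(placement_bias_coefs . z)` where `z` are the standardized static
#' covariates (elevation, slope, distance to road / village / district), then
#' region-grows each seed to a contiguous patch of `zone_area_px` pixels.
#' All-zero coefficients give uniform placement over eligible pixels. Zones
#' are mutually disjoint and disjoint from the exclusion masks, which are
#' generated here as grown patches of water, protected area and concession.
#' Each zone is assigned an establishment year from
#' `config$establishment_years` (balanced allocation, randomly permuted).
#'
#' @param config A [scenario_config()].
#' @param surfaces Matching [generate_surfaces()] output.
#' @param panel Matching [simulate_panel()] output (geometry check only).
#' @return List with `zones` (a `zone_set`) and `ground_truth` (a data frame
#'   of per-zone establishment year and injected cohort effects, per the
#'   cohort formula `effect + cohort_effect_slope * (est_year - min)`).
#' @export
place_zones <- function(config, surfaces, panel) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  npx <- nr * nc
  with_seed(child_seed(config$seed, 3), {
    # exclusion masks: water, protected area, concession patches
    masks <- list(water = logical(npx), protected_area = logical(npx),
                  concession = logical(npx))
    avail_excl <- rep(TRUE, npx)
    if (config$n_exclusions > 0) {
      types <- rep_len(names(masks), config$n_exclusions)
      for (k in seq_len(config$n_exclusions)) {
        seed_px <- sample(which(avail_excl), 1L)
        patch <- grow_patch(seed_px, config$exclusion_area_px, avail_excl, nr, nc)
        masks[[types[k]]][patch] <- TRUE
        avail_excl[patch] <- FALSE
      }
    }
    excluded <- masks$water | masks$protected_area | masks$concession

    zone_id <- matrix(0L, nr, nc)
    zones_df <- data.frame(zone_id = integer(0), est_year = integer(0),
                           area_px = integer(0), seed_row = integer(0),
                           seed_col = integer(0))
    if (config$n_zones > 0) {
      Z <- cbind(elevation = as.vector(surfaces$elevation),
                 slope = as.vector(surfaces$slope),
                 dist_road = as.vector(surfaces$dist_road),
                 dist_village = as.vector(surfaces$dist_village),
                 dist_district = as.vector(surfaces$dist_district))
      zs <- standardize_cols(Z)
      b <- as.numeric(config$placement_bias_coefs)[zs$kept]
      eta <- as.vector(zs$x %*% b)
      pseed <- plogis(eta)

      available <- !excluded
      est_alloc <- sample(rep_len(config$establishment_years, config$n_zones))
      min_patch <- max(1L, config$zone_area_px %/% 4L)
      for (zid in seq_len(config$n_zones)) {
        patch <- NULL
        for (attempt in 1:50) {   # a seed can land in an enclosed pocket
          cand <- which(available)
          if (length(cand) == 0)
            stopf("cannot place %d disjoint zones: eligible pixels exhausted after %d zones",
                  config$n_zones, zid - 1L)
          seed_px <- cand[sample.int(length(cand), 1L, prob = pseed[cand])]
          patch <- grow_patch(seed_px, config$zone_area_px, available, nr, nc)
          if (length(patch) >= min_patch) break
          patch <- NULL
        }
        if (is.null(patch))
          stopf("cannot place zone %d of %d: region growing repeatedly stalled below %d pixels",
                zid, config$n_zones, min_patch)
        zone_id[patch] <- zid
        available[patch] <- FALSE
        zones_df <- rbind(zones_df, data.frame(
          zone_id = zid, est_year = est_alloc[zid],
          area_px = length(patch),
          seed_row = ((seed_px - 1L) %% nr),
          seed_col = ((seed_px - 1L) %/% nr)))
      }
    }

    zones <- list(zone_id = zone_id, zones = zones_df,
                  exclusions = lapply(masks, matrix, nrow = nr, ncol = nc),
                  rows = nr, cols = nc, cell_size = config$cell_size)
    class(zones) <- "zone_set"

    d_est <- zones_df$est_year - if (nrow(zones_df)) min(zones_df$est_year) else 0L
    ground_truth <- data.frame(
      zone_id = zones_df$zone_id,
      est_year = zones_df$est_year,
      level_effect = config$effect_level + config$cohort_effect_slope * d_est,
      trend_effect = config$effect_trend + config$cohort_effect_slope * d_est,
      hazard_reduction = rep(config$hazard_reduction, nrow(zones_df)))
    list(zones = zones, ground_truth = ground_truth)
  })
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones (%d px) on %d x %d grid; exclusions: %s\n",
              nrow(x$zones), sum(x$zone_id > 0), x$rows, x$cols,
              paste(sprintf("%s=%d", names(x$exclusions),
                            vapply(x$exclusions, sum, 0L)), collapse = ", ")))
  invisible(x)
}
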