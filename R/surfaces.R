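# Synthetic static covariate surfaces: terrain and access features.

#' Spatially autocorrelated Gaussian random field
#'
#' White noise smoothed with a separable Gaussian kernel (truncated at three
#' standard deviations, edge-renormalized) and restandardized to zero mean,
#' unit variance. The smoothing scale sets the spatial correlation range.
#'
#' @param rows,cols Grid dimensions.
#' @param sigma_px Gaussian smoothing scale in pixels.
#' @return Matrix `rows x cols`, mean 0 and SD 1.
#' @export
gaussian_field <- function(rows, cols, sigma_px) {
  z <- matrix(rnorm(rows * cols), rows, cols)
  if (sigma_px > 0) {
    half <- max(1L, ceiling(3 * sigma_px))
    w <- exp(-0.5 * ((-half:half) / sigma_px)^2)
    sm_op <- function(n) {
      K <- matrix(0, n, n)
      for (o in -half:half) {
        i <- seq_len(n)
        j <- i + o
        ok <- j >= 1 & j <= n
        K[cbind(i[ok], j[ok])] <- w[o + half + 1]
      }
      K / rowSums(K)
    }
    z <- sm_op(rows) %*% z %*% t(sm_op(cols))
  }
  (z - mean(z)) / sd(z)
}

random_boundary_point <- function(rows, cols, cell_size) {
  w <- cols * cell_size; h <- rows * cell_size
  side <- sample.int(4, 1)
  switch(side,
         c(runif(1, 0, w), 0),
         c(runif(1, 0, w), h),
         c(0, runif(1, 0, h)),
         c(w, runif(1, 0, h)))
}

#' Generate static covariate surfaces for a scenario
#'
#' Builds the five static confounder rasters: a spatially autocorrelated
#' elevation surface, slope derived from it by Horn's method, and Euclidean
#' distance rasters to randomly placed roads (polylines), villages and
#' district centers (points). Deterministic given the scenario seed.
#'
#' @param config A [scenario_config()].
#' @return A `landscape_surfaces` object: list with matrices `elevation`
#'   (m), `slope` (deg), `dist_road`, `dist_village`, `dist_district` (m),
#'   the generating `features`, and grid geometry.
#' @export
generate_surfaces <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$grid_rows; nc <- config$grid_cols; cs <- config$cell_size
  with_seed(child_seed(config$seed, 1), {
    sigma_px <- config$corr_range / cs
    elevation <- 200 + 150 * gaussian_field(nr, nc, sigma_px)
    elevation <- pmax(elevation, 0)

    roads <- do.call(rbind, lapply(seq_len(config$n_roads), function(i) {
      a <- random_boundary_point(nr, nc, cs)
      m <- c(runif(1, 0.25, 0.75) * nc * cs, runif(1, 0.25, 0.75) * nr * cs)
      b <- random_boundary_point(nr, nc, cs)
      data.frame(x1 = c(a[1], m[1]), y1 = c(a[2], m[2]),
                 x2 = c(m[1], b[1]), y2 = c(m[2], b[2]))
    }))
    villages <- data.frame(x = runif(config$n_villages, 0, nc * cs),
                           y = runif(config$n_villages, 0, nr * cs))
    districts <- data.frame(x = runif(config$n_districts, 0, nc * cs),
                            y = runif(config$n_districts, 0, nr * cs))

    out <- list(
      elevation = elevation,
      slope = slope_from_dem(elevation, cs),
      dist_road = feature_distance_raster(nr, nc, cs, list(segments = roads)),
      dist_village = feature_distance_raster(nr, nc, cs, list(points = villages)),
      dist_district = feature_distance_raster(nr, nc, cs, list(points = districts)),
      features = list(roads = roads, villages = villages, districts = districts),
      rows = nr, cols = nc, cell_size = cs)
    class(out) <- "landscape_surfaces"
    out
  })
}

#' @export
print.landscape_surfaces <- function(x, ...) {
  cat(sprintf("<landscape_surfaces> %d x %d @ %gm; elevation %.0f-%.0f m, %d road segments, %d villages\n",
              x$rows, x$cols, x$cell_size, min(x$elevation), max(x$elevation),
              nrow(x$features$roads), nrow(x$features$villages)))
  invisible(x)
}
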