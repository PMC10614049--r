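# Potentially confounding variables: terrain, access distances, and initial
# forest condition at a reference (establishment) year.

#' Slope raster from a DEM (Horn's method)
#'
#' Computes slope in degrees with the standard 3x3 Horn finite-difference
#' stencil. Border pixels use one-sided differences (linear extrapolation of
#' the DEM by one pixel), so a tilted plane has constant slope everywhere.
#'
#' @param elevation Numeric matrix of elevations (m), rows x cols.
#' @param cell_size Pixel edge length in meters.
#' @return Matrix of slope in degrees, same shape.
#' @examples
#' dem <- outer(rep(0, 5), seq(0, 120, by = 30), "+") # rises 30 m per pixel
#' slope_from_dem(dem, 30)[3, 3] # 45 degrees
#' @export
slope_from_dem <- function(elevation, cell_size) {
  z <- as.matrix(elevation)
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2)
    stopf("slope undefined for a %dx%d raster; need at least 2x2", nr, nc)
  # pad by linear extrapolation: central difference at the edge becomes the
  # interior one-sided difference
  zp <- matrix(0, nr + 2, nc + 2)
  zp[2:(nr + 1), 2:(nc + 1)] <- z
  zp[1, 2:(nc + 1)] <- 2 * z[1, ] - z[2, ]
  zp[nr + 2, 2:(nc + 1)] <- 2 * z[nr, ] - z[nr - 1, ]
  zp[, 1] <- 2 * zp[, 2] - zp[, 3]
  zp[, nc + 2] <- 2 * zp[, nc + 1] - zp[, nc]
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  gx <- ((zp[i - 1, j + 1] + 2 * zp[i, j + 1] + zp[i + 1, j + 1]) -
         (zp[i - 1, j - 1] + 2 * zp[i, j - 1] + zp[i + 1, j - 1])) / (8 * cell_size)
  gy <- ((zp[i + 1, j - 1] + 2 * zp[i + 1, j] + zp[i + 1, j + 1]) -
         (zp[i - 1, j - 1] + 2 * zp[i - 1, j] + zp[i - 1, j + 1])) / (8 * cell_size)
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

#' Euclidean distance from points to the nearest feature
#'
#' Planar distance from `(x, y)` to the nearest geometry in a feature layer
#' holding point features (villages, district centers) and/or line segments
#' (roads, as a data frame of segment endpoints).
#'
#' @param x,y Numeric vectors of query coordinates (m).
#' @param features List with optional elements `points` (data frame with
#'   columns `x`, `y`) and `segments` (data frame with columns
#'   `x1`, `y1`, `x2`, `y2`).
#' @return Numeric vector of distances (m).
#' @export
euclidean_distance <- function(x, y, features) {
  npts <- if (!is.null(features$points)) nrow(features$points) else 0L
  nseg <- if (!is.null(features$segments)) nrow(features$segments) else 0L
  if (npts + nseg == 0L) stopf("feature layer is empty")
  d <- rep(Inf, length(x))
  if (npts > 0) {
    for (k in seq_len(npts)) {
      d <- pmin(d, sqrt((x - features$points$x[k])^2 +
                        (y - features$points$y[k])^2))
    }
  }
  if (nseg > 0) {
    s <- features$segments
    for (k in seq_len(nseg)) {
      ax <- s$x1[k]; ay <- s$y1[k]; bx <- s$x2[k]; by <- s$y2[k]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx^2 + vy^2
      tt <- if (len2 == 0) rep(0, length(x)) else
        clip(((x - ax) * vx + (y - ay) * vy) / len2, 0, 1)
      d <- pmin(d, sqrt((x - (ax + tt * vx))^2 + (y - (ay + tt * vy))^2))
    }
  }
  d
}

#' Distance-to-feature raster over a full grid
#'
#' Convenience wrapper evaluating [euclidean_distance()] at every pixel
#' center of a `rows x cols` grid.
#' @inheritParams euclidean_distance
#' @param rows,cols Grid dimensions.
#' @param cell_size Pixel edge length (m).
#' @return Matrix `rows x cols` of distances (m).
#' @export
feature_distance_raster <- function(rows, cols, cell_size, features) {
  cc <- ((seq_len(cols) - 1) + 0.5) * cell_size
  rr <- ((seq_len(rows) - 1) + 0.5) * cell_size
  x <- rep(cc, each = rows)
  y <- rep(rr, times = cols)
  matrix(euclidean_distance(x, y, features), rows, cols)
}

#' Grid (8-neighbor path) distance transform to nonforest
#'
#' Shortest-path distance over the 8-connected grid graph, with orthogonal
#' steps costing `cell_size` and diagonal steps `cell_size * sqrt(2)`, from
#' every pixel to the nearest nonforest pixel. Nonforest pixels get 0. This
#' mirrors the cost-path "gridDistance" convention used for raster
#' confounders. Computed by an iterated two-scan chamfer transform (exact for
#' this metric on an unobstructed grid).
#'
#' @param forest Logical (or 0/1) matrix; `TRUE`/1 = forest.
#' @param cell_size Pixel edge length (m).
#' @return Matrix of distances (m). If the layer has no nonforest pixel at
#'   all, every cell gets the sentinel `(rows + cols) * cell_size` and a
#'   warning is raised.
#' @export
grid_distance_transform <- function(forest, cell_size) {
  f <- as.matrix(forest)
  target <- !(f > 0)   # nonforest pixels are the destination set
  if (!any(target)) {
    warnf("no nonforest pixel in layer; returning sentinel distance")
    return(matrix((nrow(f) + ncol(f)) * cell_size, nrow(f), ncol(f)))
  }
  chamfer_dt_cpp(target, cell_size)
}

#' Grid path distance from sample pixels to the nearest nonforest pixel
#'
#' @param forest Logical matrix of forest state at the reference year.
#' @param row,col 0-based grid indices of the sample pixels.
#' @param cell_size Pixel edge length (m).
#' @return Numeric vector of distances (m); 0 where the sample pixel itself
#'   is nonforest.
#' @export
grid_distance_to_nonforest <- function(forest, row, col, cell_size) {
  dt <- grid_distance_transform(forest, cell_size)
  dt[cbind(row + 1L, col + 1L)]
}

#' Lattice offsets of pixels whose centers fall within a buffer radius
#' @noRd
buffer_offsets <- function(radius, cell_size) {
  m <- floor(radius / cell_size)
  g <- expand.grid(dr = -m:m, dc = -m:m)
  g[cell_size * sqrt(g$dr^2 + g$dc^2) <= radius, , drop = FALSE]
}

#' Proportion of forest within a circular buffer
#'
#' Fraction of pixels whose centers lie within `radius` of the sample pixel
#' center (the sample pixel itself included) that are forest. With the
#' default 126 m radius on a 30-m grid the buffer holds exactly 57 pixels
#' (a 5-ha disc). Forest inside exclusion areas counts: the buffer is a
#' pure raster neighborhood.
#'
#' @inheritParams grid_distance_to_nonforest
#' @param radius Buffer radius in meters (default 126).
#' @return Numeric vector of proportions in `[0, 1]`.
#' @export
buffer_forest_proportion <- function(forest, row, col, cell_size, radius = 126) {
  f <- as.matrix(forest) > 0
  off <- buffer_offsets(radius, cell_size)
  nr <- nrow(f); nc <- ncol(f)
  r1 <- row + 1L; c1 <- col + 1L
  m <- floor(radius / cell_size)
  if (any(r1 - m < 1 | r1 + m > nr | c1 - m < 1 | c1 + m > nc))
    stopf("buffer of radius %g m extends beyond the raster for some samples; filter border buffers first", radius)
  acc <- numeric(length(row))
  for (k in seq_len(nrow(off))) {
    acc <- acc + f[cbind(r1 + off$dr[k], c1 + off$dc[k])]
  }
  acc / nrow(off)
}

#' Buffer forest-proportion raster
#'
#' Moving-window version of [buffer_forest_proportion()] over the whole
#' grid (edge pixels, whose buffer would leave the raster, get `NA`).
#' @inheritParams buffer_forest_proportion
#' @return Matrix of proportions with `NA` in the border margin.
#' @export
buffer_forest_raster <- function(forest, cell_size, radius = 126) {
  f <- as.matrix(forest) > 0
  off <- buffer_offsets(radius, cell_size)
  m <- floor(radius / cell_size)
  disc_count_cpp(f, as.integer(off$dr), as.integer(off$dc), m) / nrow(off)
}

#' Assemble the nine matching confounders for a set of samples
#'
#' Evaluates, for each sample pixel, the nine potentially confounding
#' variables at a reference year (the establishment year of the phase being
#' matched): elevation, slope, distance to nearest road / village / district
#' center, forest state and TCC at the reference year, grid path distance to
#' nonforest at the reference year, and the proportion of forest within a
#' 5-ha (126 m) buffer at the reference year.
#'
#' @param samples Sample data frame with 0-based `row`, `col` and
#'   `sample_id` columns (see [draw_samples()]).
#' @param surfaces A `landscape_surfaces` object (static covariate rasters
#'   and access features).
#' @param panel A `landscape_panel`.
#' @param ref_year Reference calendar year (must be in `panel$years`).
#' @param buffer_radius Buffer radius in meters for the forest-proportion
#'   covariate.
#' @param layers Optional precomputed year layers from
#'   [covariate_year_layers()] (used by the phased matcher to avoid
#'   recomputing distance transforms).
#' @return Data frame keyed by `sample_id` with the nine covariate columns
#'   and `ref_year`.
#' @export
assemble_covariates <- function(samples, surfaces, panel, ref_year,
                                buffer_radius = 126, layers = NULL) {
  if (!ref_year %in% panel$years)
    stopf("ref_year %d outside panel years %d-%d", ref_year,
          min(panel$years), max(panel$years))
  if (is.null(layers))
    layers <- covariate_year_layers(panel, ref_year, buffer_radius)
  idx <- cbind(samples$row + 1L, samples$col + 1L)
  xy <- pixel_xy(samples$row, samples$col, panel$cell_size)
  data.frame(
    sample_id = samples$sample_id,
    ref_year = ref_year,
    elevation = surfaces$elevation[idx],
    slope = surfaces$slope[idx],
    dist_road = surfaces$dist_road[idx],
    dist_village = surfaces$dist_village[idx],
    dist_district = surfaces$dist_district[idx],
    forest_at_est = as.numeric(layers$forest[idx]),
    tcc_at_est = layers$tcc[idx],
    dist_nonforest_at_est = layers$dist_nonforest[idx],
    forest_prop_buffer_at_est = layers$forest_prop[idx]
  )
}

#' Precompute the time-varying covariate layers for one reference year
#'
#' @inheritParams assemble_covariates
#' @return List with `tcc`, `forest`, `dist_nonforest` and `forest_prop`
#'   matrices for `ref_year`.
#' @export
covariate_year_layers <- function(panel, ref_year, buffer_radius = 126) {
  yi <- match(ref_year, panel$years)
  if (is.na(yi)) stopf("ref_year %d not in panel", ref_year)
  forest <- panel$forest[, , yi]
  list(tcc = panel$tcc[, , yi],
       forest = forest,
       dist_nonforest = grid_distance_transform(forest, panel$cell_size),
       forest_prop = buffer_forest_raster(forest, panel$cell_size,
                                          buffer_radius))
}

#' Names of the covariates entering the propensity model
#' @param exact_var Covariate handled by exact matching (dropped from the
#'   propensity set), or `NULL`.
#' @return Character vector of covariate column names.
#' @export
propensity_covariates <- function(exact_var = "forest_at_est") {
  all9 <- c("elevation", "slope", "dist_road", "dist_village",
            "dist_district", "forest_at_est", "tcc_at_est",
            "dist_nonforest_at_est", "forest_prop_buffer_at_est")
  setdiff(all9, exact_var)
}
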