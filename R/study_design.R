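# Sample frame construction: forest reclassification, exclusion masking,
# random sampling and border-buffer filtering.

#' Reclassify land-cover labels to a binary forest layer
#'
#' Natural forest and plantation forest are forest (1); every other class,
#' including all disturbance classes, is nonforest (0).
#'
#' @param landcover Matrix (or vector) of land-cover labels: either
#'   characters/factors from the declared label set, or integer codes into
#'   `levels`.
#' @param levels Character vector naming the integer codes (defaults to the
#'   generator's five classes).
#' @return Integer matrix/vector of 0/1 with the input shape.
#' @examples
#' reclassify_forest(c("plantation_forest", "urban_water", "disturbance"))
#' @export
reclassify_forest <- function(landcover, levels = LANDCOVER_LEVELS) {
  known <- c("natural_forest", "plantation_forest", "agriculture",
             "grass_shrub", "urban_water", "disturbance")
  if (length(landcover) == 0) return(landcover)
  if (is.numeric(landcover)) {
    lab <- levels[as.integer(landcover)]
    if (anyNA(lab))
      stopf("unknown land-cover code(s): %s",
            paste(unique(landcover[is.na(lab)]), collapse = ", "))
  } else {
    lab <- as.character(landcover)
  }
  bad <- setdiff(unique(lab), known)
  if (length(bad))
    stopf("unknown land-cover label(s): %s", paste(bad, collapse = ", "))
  out <- ifelse(lab %in% c("natural_forest", "plantation_forest"), 1L, 0L)
  if (is.matrix(landcover)) dim(out) <- dim(landcover)
  out
}

#' Rectangle exclusion mask from map coordinates
#'
#' Marks pixels whose CENTERS fall inside the axis-aligned rectangle
#' `[xmin, xmax] x [ymin, ymax]` (map meters, origin at the grid corner).
#'
#' @param rows,cols Grid dimensions.
#' @param cell_size Pixel edge (m).
#' @param xmin,xmax,ymin,ymax Rectangle bounds (m).
#' @return Logical matrix.
#' @export
rect_mask <- function(rows, cols, cell_size, xmin, xmax, ymin, ymax) {
  cx <- ((seq_len(cols) - 1) + 0.5) * cell_size
  cy <- ((seq_len(rows) - 1) + 0.5) * cell_size
  outer(cy >= ymin & cy <= ymax, cx >= xmin & cx <= xmax, "&")
}

#' Eligible-pixel mask
#'
#' A pixel is eligible when its center falls outside every exclusion mask
#' (water, protected areas, concessions). Zone membership does NOT affect
#' eligibility: both treated and control samples are drawn from this frame.
#'
#' @param panel A `landscape_panel` (geometry reference).
#' @param zones A `zone_set` whose `exclusions` list is applied; or `NULL`
#'   for no exclusions.
#' @param extra_masks Optional list of additional logical matrices to
#'   exclude.
#' @return Logical matrix, `TRUE` = eligible.
#' @export
eligible_pixels <- function(panel, zones = NULL, extra_masks = NULL) {
  elig <- matrix(TRUE, panel$rows, panel$cols)
  masks <- c(if (!is.null(zones)) zones$exclusions, extra_masks)
  for (m in masks) {
    if (!identical(dim(m), dim(elig)))
      stopf("exclusion mask dims %s do not match grid %s",
            paste(dim(m), collapse = "x"), paste(dim(elig), collapse = "x"))
    elig <- elig & !m
  }
  elig
}

#' Simple random sample of eligible pixels
#'
#' Draws `floor(fraction * n_eligible)` pixels without replacement,
#' deterministically for a given seed. The sparse sampling (the study design
#' uses 1%) limits pseudoreplication from spatially autocorrelated outcomes.
#'
#' @param mask Logical eligibility matrix from [eligible_pixels()].
#' @param fraction Sampling fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @param cell_size Pixel edge (m), for the map coordinates of the points.
#' @return Data frame of sample points: `sample_id`, 0-based `row`/`col`,
#'   map coordinates `x`/`y` (m, pixel centers).
#' @export
draw_samples <- function(mask, fraction, seed, cell_size = 30) {
  if (!(fraction > 0 && fraction <= 1))
    stopf("fraction must be in (0, 1], got %g", fraction)
  elig <- which(mask)
  n <- floor(fraction * length(elig))
  px <- with_seed(seed, sort(sample(elig, n)))
  nr <- nrow(mask)
  row <- ((px - 1L) %% nr)
  col <- ((px - 1L) %/% nr)
  xy <- pixel_xy(row, col, cell_size)
  data.frame(sample_id = seq_along(px), row = row, col = col,
             x = xy$x, y = xy$y)
}

#' Label samples as treated (inside a zone) or control
#'
#' Treated samples get the zone id and establishment year of the zone whose
#' pixels contain them; controls get `NA` establishment year until matching
#' assigns them their partner's.
#'
#' @param samples Data frame from [draw_samples()].
#' @param zones A `zone_set`.
#' @return The sample data frame with `group`, `zone_id`, `est_year` added.
#' @export
assign_groups <- function(samples, zones) {
  zid <- zones$zone_id[cbind(samples$row + 1L, samples$col + 1L)]
  samples$zone_id <- ifelse(zid > 0L, zid, NA_integer_)
  samples$group <- ifelse(zid > 0L, "treated", "control")
  samples$est_year <- zones$zones$est_year[match(samples$zone_id,
                                                 zones$zones$zone_id)]
  samples
}

#' Drop samples whose buffer disc crosses the study boundary
#'
#' Keeps only samples whose full `radius`-buffer disc lies inside the
#' (rectangular) study boundary, so the buffered forest-proportion
#' confounder is always computable. Buffers crossing water, protected-area
#' or concession exclusions are deliberately RETAINED; only the outer study
#' boundary disqualifies.
#'
#' @param samples Sample data frame with `x`, `y` columns (m).
#' @param boundary Numeric vector `c(xmin, ymin, xmax, ymax)` (m).
#' @param radius Buffer radius in meters (default 126, a 5-ha disc).
#' @return Filtered sample data frame.
#' @export
filter_border_buffers <- function(samples, boundary, radius = 126) {
  keep <- samples$x - radius >= boundary[1] &
    samples$y - radius >= boundary[2] &
    samples$x + radius <= boundary[3] &
    samples$y + radius <= boundary[4]
  samples[keep, , drop = FALSE]
}

#' Grid extent as a boundary rectangle
#' @param panel A `landscape_panel` (or anything with rows/cols/cell_size).
#' @return `c(xmin, ymin, xmax, ymax)` in meters.
#' @export
grid_boundary <- function(panel) {
  c(0, 0, panel$cols * panel$cell_size, panel$rows * panel$cell_size)
}
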