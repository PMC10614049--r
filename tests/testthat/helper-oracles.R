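# Independent oracles used by the property tests. Each re-derives the
# quantity by a different route than the implementation under test.

# Dijkstra on the 8-connected grid graph (igraph): distance from pixel
# (row0, col0), 0-based, to the nearest nonforest pixel.
dijkstra_grid_distance <- function(forest, row0, col0, cell_size) {
  f <- as.matrix(forest) > 0
  nr <- nrow(f); nc <- ncol(f)
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      from <- c(from, id(r, c)); to <- c(to, id(r2, c2))
      w <- c(w, cell_size * sqrt(dr^2 + dc^2))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(nr * nc)))
  targets <- which(!f)
  if (length(targets) == 0) return(NA_real_)
  src <- id(row0 + 1L, col0 + 1L)
  d <- igraph::distances(g, v = as.character(src),
                         to = as.character(targets))
  min(d)
}

# Brute-force Mann-Kendall S by explicit double loop.
mk_bruteforce_S <- function(x) {
  n <- length(x); S <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[j] - x[i])
  S
}

# Step-by-step simulation of greedy exact + nearest-neighbor matching
# without replacement: same documented rules, different implementation.
greedy_match_oracle <- function(treated, controls) {
  if (is.null(treated$stratum)) treated$stratum <- 0
  if (is.null(controls$stratum)) controls$stratum <- 0
  avail <- rep(TRUE, nrow(controls))
  out <- NULL
  for (s in sort(unique(treated$stratum))) {
    tr <- treated[treated$stratum == s, , drop = FALSE]
    tr <- tr[order(-tr$score, tr$sample_id), , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      cand <- which(avail & controls$stratum == s)
      if (length(cand) == 0) next
      d <- abs(controls$score[cand] - tr$score[i])
      pick <- cand[order(d, controls$score[cand], controls$sample_id[cand])[1]]
      avail[pick] <- FALSE
      out <- rbind(out, data.frame(treated_id = tr$sample_id[i],
                                   control_id = controls$sample_id[pick]))
    }
  }
  out
}

# OLS through the normal equations.
ols_normal_equations <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Small scenario used across tests (fast: ~0.1 s to simulate).
tiny_scenario <- function(seed = 1, ...) {
  base <- list(grid_rows = 64, grid_cols = 64,
               years = 2000:2018, n_zones = 6,
               establishment_years = 2006:2011, zone_area_px = 60,
               n_villages = 8, n_roads = 2, n_exclusions = 2,
               exclusion_area_px = 30, seed = seed)
  do.call(scenario_config, utils::modifyList(base, list(...)))
}

# run_config for tiny scenarios: per-cohort samples are far too few for the
# 0.25 SMD screen to be anything but noise at this grid size, so plumbing
# tests relax it (the screen itself is tested directly and at full scale).
tiny_run <- function(cfg, ...) {
  args <- utils::modifyList(list(scenario = cfg, sampling_fraction = 0.6,
                                 smd_threshold = 2, forest_only = FALSE),
                            list(...))
  do.call(run_config, args)
}

# Hand-built panel wrapper around explicit arrays, for unit tests that need
# exact control over the outcome values.
manual_panel <- function(tcc, forest, years, cell_size = 30) {
  nr <- dim(tcc)[1]; nc <- dim(tcc)[2]
  dimnames(tcc) <- list(NULL, NULL, years)
  dimnames(forest) <- list(NULL, NULL, years)
  structure(list(years = years, rows = nr, cols = nc,
                 cell_size = cell_size, tcc = tcc, forest = forest,
                 landcover = ifelse(forest, 1L, 3L)),
            class = "landscape_panel")
}
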