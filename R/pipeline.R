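# End-to-end orchestration: generate -> sample -> covariates -> match ->
# event panel -> inference, plus the replication harness used for
# parameter-recovery and type-I experiments.

#' Run configuration
#'
#' Bundles everything one pipeline run needs. Exactly one of `scenario`
#' (synthetic mode) or `data` (a pre-built landscape: list with `surfaces`,
#' `panel`, `zones`, `ground_truth`) must be supplied.
#'
#' @param scenario A [scenario_config()] for synthetic mode, or `NULL`.
#' @param data Pre-built landscape list, or `NULL`.
#' @param sampling_fraction Fraction of eligible pixels sampled. The
#'   national-scale design uses 0.01 over ~130 million pixels; the
#'   desk-scale default is 0.5, the smallest fraction at which per-cohort
#'   sample sizes (~300) make the absolute-SMD 0.25 balance screen a test
#'   of structure rather than of SMD sampling noise.
#' @param buffer_radius Buffer radius (m) for the forest-proportion
#'   confounder and the border filter.
#' @param smd_threshold Absolute-SMD acceptability bound for phase
#'   filtering.
#' @param t_post_max Last post-establishment event time used by the
#'   post-trend and cohort regressions.
#' @param outcomes Outcomes to analyse, subset of `c("tcc", "forest")`.
#' @param forest_only Also run the forest-throughout matching and analysis?
#' @param seed Integer seed for the sampling stage (defaults to the
#'   scenario seed; mandatory when `data` is supplied).
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL, data = NULL, sampling_fraction = 0.5,
                       buffer_radius = 126, smd_threshold = 0.25,
                       t_post_max = 9, outcomes = c("tcc", "forest"),
                       forest_only = FALSE, seed = NULL) {
  if (is.null(scenario) == is.null(data))
    stopf("supply exactly one of `scenario` or `data`")
  if (is.null(seed)) {
    if (!is.null(scenario)) seed <- scenario$seed
    else stopf("`seed` is mandatory when running on supplied data")
  }
  structure(list(scenario = scenario, data = data,
                 sampling_fraction = sampling_fraction,
                 buffer_radius = buffer_radius,
                 smd_threshold = smd_threshold, t_post_max = t_post_max,
                 outcomes = match.arg(outcomes, c("tcc", "forest"),
                                      several.ok = TRUE),
                 forest_only = isTRUE(forest_only), seed = as.integer(seed)),
            class = "run_config")
}

#' Execute the full evaluation pipeline
#'
#' Runs, in order: landscape generation (synthetic mode), eligibility and
#' random sampling, border-buffer filtering, group labelling, per-phase
#' covariate assembly, phased exact + propensity matching, balance
#' filtering, event-time difference series (pooled and per stratum), ITS
#' fits, post-establishment trend fits, establishment-year cohort
#' regressions and Mann-Kendall screens.
#'
#' @param config A [run_config()] (or a bare [scenario_config()], which is
#'   wrapped with defaults).
#' @return A `run_result` list with every intermediate artifact and a
#'   `manifest` recording the configuration and seeds.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "scenario_config")) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))

  land <- if (!is.null(config$scenario)) simulate_landscape(config$scenario)
          else config$data
  panel <- land$panel; zones <- land$zones; surfaces <- land$surfaces

  elig <- eligible_pixels(panel, zones)
  samples <- draw_samples(elig, config$sampling_fraction,
                          seed = child_seed(config$seed, 4),
                          cell_size = panel$cell_size)
  samples <- filter_border_buffers(samples, grid_boundary(panel),
                                   radius = config$buffer_radius)
  samples <- assign_groups(samples, zones)
  if (!any(samples$group == "treated"))
    stopf("pipeline stage 'sampling': no treated samples drawn")

  phase_years <- sort(unique(samples$est_year[samples$group == "treated"]))
  cov_by_year <- lapply(phase_years, function(y)
    assemble_covariates(samples, surfaces, panel, y,
                        buffer_radius = config$buffer_radius))
  names(cov_by_year) <- phase_years

  match_raw <- phased_match(samples, cov_by_year)
  pre_balance <- pooled_pre_balance(match_raw)
  match <- filter_balanced_phases(match_raw, config$smd_threshold)

  retained <- sort(unique(match$pairs$phase))
  window <- pooled_window(retained, panel$years)

  outcomes_mats <- lapply(stats::setNames(config$outcomes, config$outcomes),
                          function(o) outcome_series(panel, samples, o))
  strata_pairs <- c(list(all = match$pairs),
                    stratify_by_initial_condition(match))

  series <- list(); its <- list(); post <- list(); cohort <- list()
  for (o in config$outcomes) {
    for (st in names(strata_pairs)) {
      pp <- strata_pairs[[st]]
      if (is.null(pp) || nrow(pp) < 2) next
      key <- paste(o, st, sep = ".")
      ser <- tryCatch(difference_series(pp, outcomes_mats[[o]], window,
                                        outcome = o, stratum = st),
                      error = function(e) NULL)
      if (is.null(ser)) next
      series[[key]] <- ser
      if (st == "all") its[[key]] <- fit_its(ser)
      post[[key]] <- tryCatch(fit_post_trend(ser), error = function(e) NULL)
      if (length(unique(pp$phase)) >= 2) {
        cp <- cohort_difference_panel(pp, outcomes_mats[[o]],
                                      t_post_max = min(config$t_post_max,
                                                       window[2]),
                                      outcome = o, stratum = st)
        cohort[[key]] <- tryCatch(fit_cohort_regression(cp),
                                  error = function(e) NULL)
      }
    }
  }

  forest_only_res <- NULL
  if (config$forest_only) {
    forest_only_res <- tryCatch(
      run_forest_only(samples, cov_by_year, panel, window, config),
      error = function(e) { warnf("forest-only analysis failed: %s",
                                  conditionMessage(e)); NULL })
  }

  screens <- mk_screens(series, match_raw)

  manifest <- list(
    seed = config$seed,
    sampling_fraction = config$sampling_fraction,
    smd_threshold = config$smd_threshold,
    n_samples = nrow(samples),
    n_treated = sum(samples$group == "treated"),
    n_pairs = nrow(match$pairs),
    phases = retained, excluded_phases = match$excluded_phases,
    window = window,
    scenario = if (!is.null(config$scenario))
      unclass(config$scenario)[c("grid_rows", "grid_cols", "years",
                                 "n_zones", "effect_level", "effect_trend",
                                 "cohort_effect_slope", "noise_sd", "seed")])
  manifest$years <- NULL

  out <- list(config = config, samples = samples,
              covariates_by_year = cov_by_year,
              match_raw = match_raw, match = match,
              pooled_balance_pre = pre_balance,
              pooled_balance_post = match$pooled,
              window = window, series = series, its = its,
              post_trend = post, cohort = cohort,
              forest_only = forest_only_res, mk_screens = screens,
              ground_truth = land$ground_truth, manifest = manifest)
  class(out) <- "run_result"
  out
}

# Forest-throughout analysis: restrict to samples forested in every panel
# year, rematch without the forest-at-establishment covariate, refit.
run_forest_only <- function(samples, cov_by_year, panel, window, config) {
  idx <- cbind(samples$row + 1L, samples$col + 1L)
  always_forest <- rep(TRUE, nrow(samples))
  for (yi in seq_along(panel$years))
    always_forest <- always_forest & panel$forest[, , yi][idx]
  sub <- samples[always_forest, , drop = FALSE]
  if (sum(sub$group == "treated") < 2) stopf("too few always-forest treated samples")
  mr <- phased_match(sub, cov_by_year, exact_var = NULL,
                     ps_vars = propensity_covariates("forest_at_est"))
  m <- filter_balanced_phases(mr, config$smd_threshold)
  win <- pooled_window(sort(unique(m$pairs$phase)), panel$years)
  win <- c(max(win[1], window[1]), min(win[2], window[2]))
  om <- outcome_series(panel, sub, "tcc")
  ser <- difference_series(m$pairs, om, win, outcome = "tcc",
                           stratum = "forest_throughout")
  cp <- if (length(unique(m$pairs$phase)) >= 2)
    cohort_difference_panel(m$pairs, om,
                            t_post_max = min(config$t_post_max, win[2]),
                            outcome = "tcc", stratum = "forest_throughout")
  list(match = m, series = ser, its = fit_its(ser),
       post_trend = fit_post_trend(ser),
       cohort = if (!is.null(cp)) tryCatch(fit_cohort_regression(cp),
                                           error = function(e) NULL))
}

# Pooled PRE-matching balance: all cohorts' treated vs the full initial
# control pool, each phase evaluated at its own establishment year.
pooled_pre_balance <- function(match_raw) {
  b <- match_raw$balance
  pre <- b[b$when == "pre", , drop = FALSE]
  agg <- stats::aggregate(abs(smd) ~ covariate, data = pre[pre$defined, ],
                          FUN = mean)
  names(agg) <- c("covariate", "mean_abs_smd")
  agg
}

# Mann-Kendall screens: outcome trajectories (treated / control, full and
# post window) and, across phases, the pre-matching SMD of each covariate
# (does where-CFs-go drift over establishment years?), Bonferroni-corrected.
mk_screens <- function(series, match_raw) {
  rows <- list()
  for (key in names(series)) {
    s <- series[[key]]
    for (grp in c("mean_treated", "mean_control")) {
      for (win in c("full", "post")) {
        v <- if (win == "full") s[[grp]] else s[[grp]][s$t >= 0]
        if (length(v) >= 3) {
          mk <- mann_kendall(v)
          rows[[length(rows) + 1L]] <- data.frame(
            screen = "trajectory", series = key, group = grp, window = win,
            S = mk$S, tau = mk$tau, p_value = mk$p_value)
        }
      }
    }
  }
  b <- match_raw$balance
  pre <- b[b$when == "pre" & b$defined, , drop = FALSE]
  smd_rows <- list()
  for (v in unique(pre$covariate)) {
    x <- pre$smd[pre$covariate == v][order(pre$phase[pre$covariate == v])]
    if (length(x) >= 3) {
      mk <- mann_kendall(x)
      smd_rows[[length(smd_rows) + 1L]] <- data.frame(
        screen = "smd_by_phase", series = v, group = NA, window = NA,
        S = mk$S, tau = mk$tau, p_value = mk$p_value)
    }
  }
  out <- do.call(rbind, c(rows, smd_rows))
  if (!is.null(out) && any(out$screen == "smd_by_phase")) {
    i <- out$screen == "smd_by_phase"
    out$p_bonferroni <- NA_real_
    out$p_bonferroni[i] <- bonferroni(out$p_value[i], m = sum(i))
  }
  out
}

#' @export
print.run_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<run_result> %d samples (%d treated), %d pairs over phases %s\n",
              m$n_samples, m$n_treated, m$n_pairs,
              paste(range(m$phases), collapse = "-")))
  cat(sprintf("  pooled window [%d, %d]; excluded phases: %s\n",
              m$window[1], m$window[2],
              if (length(m$excluded_phases)) paste(m$excluded_phases, collapse = ", ")
              else "none"))
  for (key in names(x$its)) {
    b2 <- its_coef(x$its[[key]], "cf_establishment")
    b3 <- its_coef(x$its[[key]], "time_since_establishment")
    cat(sprintf("  ITS %-12s level %+0.3f (p=%.3g), trend %+0.3f (p=%.3g)\n",
                key, b2["estimate"], b2["p_value"],
                b3["estimate"], b3["p_value"]))
  }
  invisible(x)
}

#' Replicate the pipeline over seeds and summarize recovery
#'
#' Runs [run_pipeline()] over `n_replicates` derived seeds and aggregates
#' the ITS level/trend estimates for the TCC difference series against the
#' scenario's injected ground truth: mean, bias, Monte-Carlo SE, RMSE, the
#' rejection rate of the level-change t-test, and the pooled max |SMD|
#' before and after matching.
#'
#' @param config A [run_config()] in synthetic mode (or a bare
#'   [scenario_config()]).
#' @param n_replicates Number of replicates (>= 2).
#' @param alpha Size of the level-change t-test tallied into
#'   `rejection_rate`.
#' @return A `replicate_summary` list: per-replicate data frame `runs` and
#'   aggregate `summary`.
#' @export
replicate_study <- function(config, n_replicates, alpha = 0.05) {
  if (inherits(config, "scenario_config")) config <- run_config(config)
  if (n_replicates < 2) stopf("need at least 2 replicates")
  if (is.null(config$scenario))
    stopf("replication requires synthetic mode (a scenario config)")

  runs <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    sc <- config$scenario
    sc$seed <- child_seed(config$seed, 100 + i)
    cfg_i <- config; cfg_i$scenario <- sc; cfg_i$seed <- sc$seed
    r <- run_pipeline(cfg_i)
    key <- "tcc.all"
    b2 <- its_coef(r$its[[key]], "cf_establishment")
    b3 <- its_coef(r$its[[key]], "time_since_establishment")
    post_b <- r$pooled_balance_post
    pre_b <- r$pooled_balance_pre
    inter <- NA_real_
    ck <- intersect(c("tcc.forest", "tcc.all"), names(r$cohort))
    if (length(ck)) {
      cf <- r$cohort[[ck[1]]]$coefficients
      inter <- cf$estimate[cf$term == "interaction"]
    }
    truth2 <- config$scenario$effect_level
    truth3 <- config$scenario$effect_trend
    crit <- stats::qt(0.975, df = r$its[[key]]$n - 4)
    runs[[i]] <- data.frame(
      replicate = i, seed = sc$seed,
      n_pairs = r$manifest$n_pairs,
      beta2 = b2[["estimate"]], beta2_se = b2[["se"]],
      beta2_p = b2[["p_value"]],
      beta2_covered = abs(b2[["estimate"]] - truth2) <= crit * b2[["se"]],
      beta3 = b3[["estimate"]], beta3_se = b3[["se"]],
      beta3_covered = abs(b3[["estimate"]] - truth3) <= crit * b3[["se"]],
      cohort_interaction = inter,
      max_smd_pre = max(pre_b$mean_abs_smd),
      max_smd_post = max(abs(post_b$smd[post_b$defined])))
  }
  runs <- do.call(rbind, runs)
  truth_level <- config$scenario$effect_level
  truth_trend <- config$scenario$effect_trend
  summary <- list(
    n_replicates = n_replicates,
    truth = c(level = truth_level, trend = truth_trend),
    beta2_mean = mean(runs$beta2), beta2_sd = sd(runs$beta2),
    beta2_mcse = sd(runs$beta2) / sqrt(n_replicates),
    beta2_bias = mean(runs$beta2) - truth_level,
    beta2_rmse = sqrt(mean((runs$beta2 - truth_level)^2)),
    beta3_mean = mean(runs$beta3), beta3_sd = sd(runs$beta3),
    beta3_mcse = sd(runs$beta3) / sqrt(n_replicates),
    beta3_bias = mean(runs$beta3) - truth_trend,
    beta3_rmse = sqrt(mean((runs$beta3 - truth_trend)^2)),
    rejection_rate = mean(runs$beta2_p < alpha),
    beta2_coverage = mean(runs$beta2_covered),
    beta3_coverage = mean(runs$beta3_covered),
    smd_post_lt_pre = mean(runs$max_smd_post < runs$max_smd_pre),
    smd_post_ok = mean(runs$max_smd_post < config$smd_threshold))
  structure(list(runs = runs, summary = summary),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<replicate_summary> %d replicates; truth level %g, trend %g\n",
              s$n_replicates, s$truth["level"], s$truth["trend"]))
  cat(sprintf("  beta2: mean %.3f (MCSE %.3f, bias %+.3f); beta3: mean %.3f (MCSE %.3f, bias %+.3f)\n",
              s$beta2_mean, s$beta2_mcse, s$beta2_bias,
              s$beta3_mean, s$beta3_mcse, s$beta3_bias))
  cat(sprintf("  level-test rejection rate %.3f; SMD post<pre in %.0f%%, post<threshold in %.0f%% of runs\n",
              s$rejection_rate, 100 * s$smd_post_lt_pre, 100 * s$smd_post_ok))
  invisible(x)
}

#' Write a synthetic landscape to plain-text files
#'
#' Emits the generator's outputs in language-agnostic form: covariate
#' surfaces and exclusion masks as headerless CSV grids (one row per raster
#' row), the zone table and ground truth as CSV, and the scenario
#' configuration as YAML.
#'
#' @param land Output of [simulate_landscape()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_landscape <- function(land, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wgrid <- function(m, f)
    utils::write.table(m, file.path(dir, f), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  for (nm in c("elevation", "slope", "dist_road", "dist_village",
               "dist_district"))
    wgrid(land$surfaces[[nm]], paste0(nm, ".csv"))
  wgrid(land$zones$zone_id, "zone_id.csv")
  for (nm in names(land$zones$exclusions))
    wgrid(land$zones$exclusions[[nm]] * 1L, paste0("exclusion_", nm, ".csv"))
  write.csv(land$zones$zones, file.path(dir, "zones.csv"), row.names = FALSE)
  write.csv(land$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  cfg <- unclass(land$config)
  cfg$placement_bias_coefs <- as.list(cfg$placement_bias_coefs)
  yaml::write_yaml(cfg, file.path(dir, "scenario.yml"))
  invisible(dir)
}

#' Write the tabular artifacts of a run to a directory
#'
#' Emits plain CSVs (samples, pairs, balance tables, event series,
#' coefficient tables, trend screens) plus a YAML manifest with the seeds
#' and configuration, so a run can be inspected or re-consumed outside R.
#'
#' @param result A `run_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest file path.
#' @export
write_run_artifacts <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wcsv(result$samples, "samples.csv")
  wcsv(result$match$pairs, "pairs.csv")
  wcsv(result$match_raw$balance, "balance_by_phase.csv")
  wcsv(result$pooled_balance_post, "pooled_balance_post.csv")
  wcsv(do.call(rbind, result$series), "event_series.csv")
  coef_tab <- do.call(rbind, lapply(names(result$its), function(k)
    cbind(series = k, result$its[[k]]$coefficients)))
  wcsv(coef_tab, "its_coefficients.csv")
  if (length(result$cohort)) {
    ctab <- do.call(rbind, lapply(names(result$cohort), function(k)
      if (!is.null(result$cohort[[k]]))
        cbind(series = k, result$cohort[[k]]$coefficients)))
    if (!is.null(ctab)) wcsv(ctab, "cohort_coefficients.csv")
  }
  if (!is.null(result$mk_screens)) wcsv(result$mk_screens, "mk_screens.csv")
  mpath <- file.path(dir, "manifest.yml")
  yaml::write_yaml(result$manifest, mpath)
  invisible(mpath)
}
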