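# Event-time realignment of matched outcomes and construction of the
# treated-minus-control difference series.

#' Per-sample outcome series from a panel
#'
#' Extracts, for each sample pixel, the annual outcome: `"tcc"` (percent) or
#' `"forest"` (0/1 state).
#'
#' @param panel A `landscape_panel`.
#' @param samples Sample data frame (0-based `row`, `col`).
#' @param outcome `"tcc"` or `"forest"`.
#' @return Numeric matrix `n_samples x n_years` (columns named by calendar
#'   year).
#' @export
outcome_series <- function(panel, samples, outcome = c("tcc", "forest")) {
  outcome <- match.arg(outcome)
  arr <- if (outcome == "tcc") panel$tcc else panel$forest * 1
  ny <- length(panel$years)
  out <- matrix(NA_real_, nrow(samples), ny,
                dimnames = list(samples$sample_id, panel$years))
  idx <- cbind(samples$row + 1L, samples$col + 1L)
  for (yi in seq_len(ny)) out[, yi] <- arr[, , yi][idx]
  out
}

#' Convert calendar-year outcomes to event time
#'
#' Event time `t = calendar_year - est_year`; the establishment year is
#' `t = 0`. Control samples inherit the establishment year of their matched
#' treated partner, which must therefore be supplied via `est_year`.
#'
#' @param outcomes Matrix from [outcome_series()] (rows = samples, columns
#'   named by calendar year).
#' @param est_year Establishment year per row (recycled if scalar).
#' @return Long data frame `sample_id`, `year`, `t`, `value`.
#' @export
to_event_time <- function(outcomes, est_year) {
  years <- as.integer(colnames(outcomes))
  est_year <- rep_len(as.integer(est_year), nrow(outcomes))
  if (anyNA(est_year))
    stopf("missing establishment year: controls must inherit their matched partner's year before event-time conversion")
  data.frame(
    sample_id = rep(rownames(outcomes), times = length(years)),
    year = rep(years, each = nrow(outcomes)),
    t = rep(years, each = nrow(outcomes)) - rep(est_year, times = length(years)),
    value = as.vector(outcomes))
}

#' Pooled event-time window shared by all cohorts
#'
#' The widest `[t_min, t_max]` over which EVERY cohort is observed:
#' `t_min = first_panel_year - min(est_years)` and
#' `t_max = last_panel_year - max(est_years)`.
#'
#' @param est_years Establishment years of the retained cohorts.
#' @param panel_years Calendar years of the outcome panel.
#' @return Integer vector `c(t_min, t_max)`.
#' @examples
#' pooled_window(1997:2010, 1989:2019) # -8 9
#' @export
pooled_window <- function(est_years, panel_years) {
  t_min <- as.integer(min(panel_years) - min(est_years))
  t_max <- as.integer(max(panel_years) - max(est_years))
  if (t_min >= t_max)
    stopf("degenerate pooled window [%d, %d]: cohorts span the whole panel",
          t_min, t_max)
  c(t_min, t_max)
}

#' Stratify matched pairs by initial land condition
#'
#' Splits pairs by the exact-matched forest state at the establishment year
#' (shared by both members of a pair): the forest-at-establishment stratum
#' measures forest conservation, the nonforest stratum forest recovery. The
#' forest-throughout stratum comes from the dedicated forest-only matching
#' run and is passed through unchanged.
#'
#' @param result A filtered `match_result` whose `pairs$stratum` carries the
#'   forest-at-establishment value.
#' @return List of pair data frames: `forest`, `nonforest`.
#' @export
stratify_by_initial_condition <- function(result) {
  p <- result$pairs
  if (is.null(result$exact_var))
    stopf("pairs were not exact-matched on forest state; strata undefined")
  list(forest = p[p$stratum == 1, , drop = FALSE],
       nonforest = p[p$stratum == 0, , drop = FALSE])
}

#' Treated-minus-control difference series over the pooled window
#'
#' For each event time `t` in the window, averages the outcome over all
#' matched treated samples and over all matched controls (each sample
#' observed at its own calendar year `est + t`), and takes the difference
#' `D(t)`. Forest-cover means are scaled to percentage points (x100) so
#' effects are in the same units as TCC.
#'
#' @param pairs Pair data frame (`treated_id`, `control_id`, `phase` = the
#'   establishment year).
#' @param outcomes Outcome matrix from [outcome_series()] covering all
#'   samples in `pairs`.
#' @param window `c(t_min, t_max)` from [pooled_window()].
#' @param outcome Label: `"tcc"` or `"forest"` (`"forest"` triggers the
#'   x100 scaling).
#' @param stratum Label stored on the series (e.g. `"all"`, `"forest"`).
#' @return An `event_series` data frame: `outcome`, `stratum`, `t`,
#'   `mean_treated`, `mean_control`, `D`, `n`.
#' @export
difference_series <- function(pairs, outcomes, window,
                              outcome = "tcc", stratum = "all") {
  if (nrow(pairs) == 0) stopf("no pairs to build a difference series from")
  years <- as.integer(colnames(outcomes))
  scale <- if (outcome == "forest") 100 else 1
  tr_rows <- match(as.character(pairs$treated_id), rownames(outcomes))
  co_rows <- match(as.character(pairs$control_id), rownames(outcomes))
  if (anyNA(tr_rows) || anyNA(co_rows))
    stopf("pairs reference samples missing from the outcome matrix")
  ts <- window[1]:window[2]
  out <- lapply(ts, function(t) {
    yi <- match(pairs$phase + t, years)
    if (anyNA(yi))
      stopf("event time %d not observed for all pairs; restrict the window", t)
    mt <- mean(outcomes[cbind(tr_rows, yi)]) * scale
    mc <- mean(outcomes[cbind(co_rows, yi)]) * scale
    data.frame(outcome = outcome, stratum = stratum, t = t,
               mean_treated = mt, mean_control = mc, D = mt - mc,
               n = nrow(pairs))
  })
  out <- do.call(rbind, out)
  class(out) <- c("event_series", "data.frame")
  out
}

#' Per-cohort difference panel for the establishment-year regressions
#'
#' Builds one difference series per establishment-year cohort, restricted to
#' post-establishment event times `t` in `[0, t_post_max]`, and stacks them
#' with the cohort year attached — the input of
#' [fit_cohort_regression()].
#'
#' @inheritParams difference_series
#' @param t_post_max Last post-establishment event time (default 9).
#' @return Data frame `est_year`, `t`, `D`, `n`, `outcome`, `stratum`.
#' @export
cohort_difference_panel <- function(pairs, outcomes, t_post_max = 9,
                                    outcome = "tcc", stratum = "all") {
  do.call(rbind, lapply(sort(unique(pairs$phase)), function(ph) {
    pp <- pairs[pairs$phase == ph, , drop = FALSE]
    s <- difference_series(pp, outcomes, c(0, t_post_max),
                           outcome = outcome, stratum = stratum)
    data.frame(est_year = ph, t = s$t, D = s$D, n = s$n,
               outcome = outcome, stratum = stratum)
  }))
}

#' @export
plot.event_series <- function(x, ...) {
  plot(x$t, x$D, type = "b", pch = 19, xlab = "years since establishment",
       ylab = sprintf("treated - control %s", x$outcome[1]),
       main = sprintf("Difference series (%s, %s stratum)",
                      x$outcome[1], x$stratum[1]), ...)
  graphics::abline(v = 0.5, lty = 2)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
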