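# Phased exact + propensity-score nearest-neighbor matching without
# replacement, with standardized-mean-difference balance assessment.

#' Standardized mean difference (treated-SD denominator)
#'
#' `(mean(treated) - mean(control)) / sd(treated)` with the `n - 1` SD of
#' the TREATED group as denominator, for continuous and binary covariates
#' alike. If the treated SD is zero the SMD is undefined: `NA` is returned
#' with a warning (never silently 0).
#'
#' @param treated,control Numeric vectors (treated needs length >= 2).
#' @return Signed SMD (scalar), or `NA` if undefined.
#' @examples
#' compute_smd(c(1, 2, 3), c(2, 3, 4)) # -1
#' @export
compute_smd <- function(treated, control) {
  if (length(treated) < 2) stopf("need >= 2 treated values for an SMD")
  s <- sd(treated)
  if (!is.finite(s) || s == 0) {
    warnf("treated-group SD is 0; SMD undefined")
    return(NA_real_)
  }
  (mean(treated) - mean(control)) / s
}

#' Propensity scores by logistic regression
#'
#' Logistic regression of the treatment indicator on the continuous
#' confounders (internally standardized; zero-variance columns dropped).
#' Under (quasi-)separation the fit falls back to a ridge-penalized logistic
#' regression with a warning, so scores stay usable for nearest-neighbor
#' matching.
#'
#' @param treated,control Data frames / matrices of covariates (same
#'   columns).
#' @return List with `score_treated`, `score_control` (fitted probabilities
#'   in `(0, 1)`) and `separation` flag.
#' @export
fit_propensity <- function(treated, control) {
  if (nrow(treated) < 1 || nrow(control) < 1)
    stopf("need at least one treated and one control unit")
  x <- rbind(as.matrix(treated), as.matrix(control))
  y <- c(rep(1L, nrow(treated)), rep(0L, nrow(control)))
  zs <- standardize_cols(x)
  z <- zs$x
  if (ncol(z) == 0) {
    p <- rep(mean(y), length(y))
    return(list(score_treated = p[y == 1], score_control = p[y == 0],
                separation = FALSE))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(1, z), y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep && any(abs(fit$coefficients[-1]) > 15, na.rm = TRUE)) sep <- TRUE
  if (sep && min(sum(y == 1), sum(y == 0)) >= 2) {
    warnf("separation detected in propensity model; using ridge-penalized fit")
    zr <- if (ncol(z) == 1) cbind(z, 0) else z   # glmnet needs >= 2 columns
    rf <- glmnet::glmnet(zr, y, family = "binomial", alpha = 0,
                         lambda = 0.05, standardize = FALSE)
    p <- as.numeric(predict(rf, newx = zr, type = "response"))
  } else {
    if (sep)
      warnf("separation detected in propensity model with a single-unit class; using clipped unpenalized scores")
    p <- fit$fitted.values
  }
  p <- clip(p, 1e-12, 1 - 1e-12)
  list(score_treated = p[y == 1], score_control = p[y == 0],
       separation = sep)
}

#' Exact + nearest-neighbor greedy matching without replacement
#'
#' Within each exact-matching stratum, treated units are processed in
#' decreasing propensity-score order (ties broken by id) and each is paired
#' with the still-unmatched control minimizing the absolute score
#' difference (distance ties broken toward the lower control score, then
#' the lower control id). No caliper; a treated unit whose stratum has no
#' controls left goes unmatched.
#'
#' @param treated Data frame with `sample_id`, `score` and optionally a
#'   `stratum` column (exact-matching value).
#' @param controls Data frame with `sample_id`, `score`, optional `stratum`.
#' @return List with `pairs` (data frame `treated_id`, `control_id`,
#'   `score_treated`, `score_control`, `stratum`) and `n_unmatched_treated`.
#' @export
exact_nn_match <- function(treated, controls) {
  if (is.null(treated$stratum)) treated$stratum <- 0
  if (is.null(controls$stratum)) controls$stratum <- 0
  pairs <- list()
  n_unmatched <- 0L
  for (s in sort(unique(treated$stratum))) {
    tr <- treated[treated$stratum == s, , drop = FALSE]
    tr <- tr[order(-tr$score, tr$sample_id), , drop = FALSE]
    co <- controls[controls$stratum == s, , drop = FALSE]
    co <- co[order(co$score, co$sample_id), , drop = FALSE]
    if (nrow(co) == 0) { n_unmatched <- n_unmatched + nrow(tr); next }
    j <- greedy_nn_cpp(tr$score, co$score)
    matched <- j > 0
    n_unmatched <- n_unmatched + sum(!matched)
    if (any(matched)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        treated_id = tr$sample_id[matched],
        control_id = co$sample_id[j[matched]],
        score_treated = tr$score[matched],
        score_control = co$score[j[matched]],
        stratum = s)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated_id = integer(0), control_id = integer(0),
               score_treated = numeric(0), score_control = numeric(0),
               stratum = numeric(0))
  list(pairs = pairs, n_unmatched_treated = n_unmatched)
}

balance_rows <- function(phase, when, tr_cov, co_cov, vars) {
  do.call(rbind, lapply(vars, function(v) {
    smd <- suppressWarnings(
      if (nrow(tr_cov) >= 2) compute_smd(tr_cov[[v]], co_cov[[v]]) else NA_real_)
    data.frame(phase = phase, when = when, covariate = v, smd = smd,
               defined = is.finite(smd),
               n_treated = nrow(tr_cov), n_control = nrow(co_cov))
  }))
}

#' Phased exact + propensity matching by establishment year
#'
#' Runs the matching cohort by cohort, oldest establishment year first. At
#' each phase the time-varying confounders are evaluated at THAT phase's
#' establishment year, for the phase's treated cohort and for every control
#' still unmatched; a propensity model is fit, treated units are exact-matched
#' on the `exact_var` stratum and nearest-neighbor matched on the score, and
#' matched controls leave the pool for all later phases (matching is without
#' replacement globally). Phases with no treated samples are skipped.
#'
#' @param samples Labelled sample frame from [assign_groups()].
#' @param covariates_by_year Named list: for each establishment year (as
#'   character), the covariate data frame of [assemble_covariates()] for ALL
#'   samples at that reference year.
#' @param exact_var Covariate matched exactly (default `forest_at_est`);
#'   `NULL` for none.
#' @param ps_vars Covariates entering the propensity model. The default is
#'   the full confounder set minus `exact_var`. The forest-throughout
#'   analysis passes `exact_var = NULL` with
#'   `ps_vars = propensity_covariates("forest_at_est")`: forest state at
#'   establishment is constant (all forest) and is dropped entirely — a
#'   configuration, not a separate code path.
#' @return A `match_result`: `pairs` (with phase), per-phase `balance` table
#'   (pre/post SMDs), `pair_covariates` (raw covariate values of matched
#'   units, for pooled balance), `excluded_phases` (none yet; see
#'   [filter_balanced_phases()]), counts.
#' @export
phased_match <- function(samples, covariates_by_year,
                         exact_var = "forest_at_est",
                         ps_vars = propensity_covariates(exact_var)) {
  treated_all <- samples[samples$group == "treated", , drop = FALSE]
  if (nrow(treated_all) == 0) stopf("no treated samples to match")
  all_vars <- unique(c(if (!is.null(exact_var)) exact_var, ps_vars))

  pool <- samples$sample_id[samples$group == "control"]
  phases <- sort(unique(treated_all$est_year))
  pairs <- list(); balance <- list(); pair_cov <- list()
  n_unmatched <- integer(0)

  for (ph in phases) {
    cov <- covariates_by_year[[as.character(ph)]]
    if (is.null(cov)) stopf("no covariates supplied for phase %d", ph)
    tr_ids <- treated_all$sample_id[treated_all$est_year == ph]
    if (length(tr_ids) == 0) next
    tr_cov <- cov[match(tr_ids, cov$sample_id), , drop = FALSE]
    co_cov <- cov[match(pool, cov$sample_id), , drop = FALSE]
    if (nrow(co_cov) == 0) {
      n_unmatched[as.character(ph)] <- length(tr_ids)
      next
    }
    balance[[length(balance) + 1L]] <-
      balance_rows(ph, "pre", tr_cov, co_cov, all_vars)

    ps <- fit_propensity(tr_cov[, ps_vars, drop = FALSE],
                         co_cov[, ps_vars, drop = FALSE])
    tr <- data.frame(sample_id = tr_ids, score = ps$score_treated)
    co <- data.frame(sample_id = pool, score = ps$score_control)
    if (!is.null(exact_var)) {
      tr$stratum <- tr_cov[[exact_var]]
      co$stratum <- co_cov[[exact_var]]
    }
    m <- exact_nn_match(tr, co)
    n_unmatched[as.character(ph)] <- m$n_unmatched_treated
    if (nrow(m$pairs) == 0) next
    m$pairs$phase <- ph
    pairs[[length(pairs) + 1L]] <- m$pairs

    mt_cov <- cov[match(m$pairs$treated_id, cov$sample_id), , drop = FALSE]
    mc_cov <- cov[match(m$pairs$control_id, cov$sample_id), , drop = FALSE]
    balance[[length(balance) + 1L]] <-
      balance_rows(ph, "post", mt_cov, mc_cov, all_vars)
    mt_cov$role <- "treated"; mc_cov$role <- "control"
    mt_cov$phase <- mc_cov$phase <- ph
    pair_cov[[length(pair_cov) + 1L]] <- rbind(mt_cov, mc_cov)

    pool <- setdiff(pool, m$pairs$control_id)
  }

  res <- list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
    balance = if (length(balance)) do.call(rbind, balance) else NULL,
    pair_covariates = if (length(pair_cov)) do.call(rbind, pair_cov) else NULL,
    covariate_names = all_vars, exact_var = exact_var,
    excluded_phases = integer(0), n_unmatched = n_unmatched)
  class(res) <- "match_result"
  stopifnot(!anyDuplicated(res$pairs$control_id),
            !anyDuplicated(res$pairs$treated_id))
  res
}

#' Pooled balance over the matched set
#'
#' SMD per covariate with all phases' matched treated (and control) values
#' pooled, each evaluated at its own phase's establishment year.
#'
#' @param result A `match_result`.
#' @param phases Optional subset of phases to pool (default: all present).
#' @return Data frame `covariate`, `smd`, `defined`, `n_treated`,
#'   `n_control`.
#' @export
pooled_balance <- function(result, phases = NULL) {
  pc <- result$pair_covariates
  if (is.null(pc)) stopf("match result holds no pairs")
  if (!is.null(phases)) pc <- pc[pc$phase %in% phases, , drop = FALSE]
  tr <- pc[pc$role == "treated", , drop = FALSE]
  co <- pc[pc$role == "control", , drop = FALSE]
  b <- balance_rows(NA, "post", tr, co, result$covariate_names)
  b$phase <- NULL; b$when <- NULL
  b
}

#' Drop phases whose post-matching balance is unacceptable
#'
#' Removes every pair belonging to a phase whose post-matching balance table
#' has any covariate with `|SMD| > threshold` (default 0.25, the
#' conventional acceptability bound), then recomputes the pooled balance on
#' the surviving pairs.
#'
#' @param result A `match_result` from [phased_match()].
#' @param threshold Absolute-SMD acceptability bound.
#' @return The filtered `match_result`, with `excluded_phases` recorded and
#'   `pooled` balance attached.
#' @export
filter_balanced_phases <- function(result, threshold = 0.25) {
  stopifnot(inherits(result, "match_result"))
  b <- result$balance
  post <- b[b$when == "post" & b$defined, , drop = FALSE]
  bad <- sort(unique(post$phase[abs(post$smd) > threshold]))
  keep <- setdiff(sort(unique(result$pairs$phase)), bad)
  if (length(keep) == 0)
    stopf("all phases exceed |SMD| threshold %g; no matched sample survives",
          threshold)
  out <- result
  out$pairs <- result$pairs[result$pairs$phase %in% keep, , drop = FALSE]
  out$pair_covariates <-
    result$pair_covariates[result$pair_covariates$phase %in% keep, , drop = FALSE]
  out$excluded_phases <- bad
  out$threshold <- threshold
  out$pooled <- pooled_balance(out)
  out
}

#' @export
print.match_result <- function(x, ...) {
  np <- if (is.null(x$pairs)) 0L else nrow(x$pairs)
  cat(sprintf("<match_result> %d pairs over %d phase(s)%s\n", np,
              length(unique(x$pairs$phase)),
              if (length(x$excluded_phases))
                sprintf(", %d phase(s) excluded for imbalance (%s)",
                        length(x$excluded_phases),
                        paste(x$excluded_phases, collapse = ", "))
              else ""))
  if (!is.null(x$pooled)) {
    mx <- max(abs(x$pooled$smd[x$pooled$defined]))
    cat(sprintf("  pooled max |SMD| = %.3f over %d covariates\n", mx,
                nrow(x$pooled)))
  }
  invisible(x)
}
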