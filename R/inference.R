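# Interrupted time-series regression, post-establishment trend and cohort
# regressions, and Mann-Kendall trend screens.

#' Segmented-regression design for the interrupted time series
#'
#' One row per event time `t` with the three regressors of the ITS model:
#' `time` (= `t`, entered on its native scale), the post-establishment
#' indicator `cf_establishment` and the elapsed time
#' `time_since_establishment`. The establishment year itself (`t = 0`) is
#' coded as PRE-intervention — both intervention terms are 0 at `t <= 0` —
#' on the hypothesis that conservation activity only becomes measurable the
#' year after establishment.
#'
#' @param window `c(t_min, t_max)` or an explicit vector of event times.
#' @return Data frame `time`, `cf_establishment`,
#'   `time_since_establishment`.
#' @examples
#' build_its_design(c(-2, 2))
#' @export
build_its_design <- function(window) {
  ts <- if (length(window) == 2) window[1]:window[2] else as.integer(window)
  if (length(ts) < 4)
    stopf("ITS design needs at least 4 time points (got %d)", length(ts))
  data.frame(time = ts,
             cf_establishment = as.integer(ts >= 1),
             time_since_establishment = ifelse(ts >= 1, ts, 0L))
}

#' Fit the interrupted time-series model to a difference series
#'
#' Ordinary least squares of `D(t)` on the segmented design
#' `D = b0 + b1*time + b2*cf_establishment + b3*time_since_establishment + e`:
#' `b1` is the pre-existing trend, `b2` the level change at establishment
#' and `b3` the trend change after establishment. Conventional homoskedastic
#' standard errors with `n - 4` degrees of freedom.
#'
#' @param series An `event_series` (needs columns `t` and `D`), or any data
#'   frame with those columns.
#' @param robust_se Use Newey-West (heteroskedasticity- and
#'   autocorrelation-consistent) standard errors instead of the
#'   conventional homoskedastic ones. Off by default: the design's
#'   conventional test is the object of the validation experiments, and an
#'   18-point series gives HAC estimators little to work with.
#' @return An `its_fit`: coefficient table (`term`, `estimate`, `se`,
#'   `t_value`, `p_value`), `n`, `r_squared`, `residuals`, `fitted` and the
#'   underlying `lm` object.
#' @export
fit_its <- function(series, robust_se = FALSE) {
  X <- build_its_design(series$t)
  dat <- cbind(D = series$D, X)
  qx <- qr(cbind(1, as.matrix(X)))
  if (qx$rank < 4) {
    cols <- c("(Intercept)", names(X))
    stopf("ITS design is rank deficient; collinear columns among: %s",
          paste(cols, collapse = ", "))
  }
  fit <- lm(D ~ time + cf_establishment + time_since_establishment, data = dat)
  sm <- suppressWarnings(summary(fit))  # noiseless series: perfect-fit warning
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "t_value", "p_value")
  if (robust_se) {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stopf("robust_se = TRUE requires the sandwich package")
    v <- sandwich::NeweyWest(fit, prewhite = FALSE)
    ct$se <- sqrt(diag(v))
    ct$t_value <- ct$estimate / ct$se
    ct$p_value <- 2 * pt(-abs(ct$t_value), df = nrow(dat) - 4)
  }
  ct <- cbind(term = c("intercept", "time", "cf_establishment",
                       "time_since_establishment"), ct)
  rownames(ct) <- NULL
  out <- list(coefficients = ct, n = nrow(dat),
              r_squared = sm$r.squared, sigma = sm$sigma,
              residuals = as.numeric(stats::residuals(fit)),
              fitted = as.numeric(stats::fitted(fit)),
              lm = fit, outcome = series$outcome[1], stratum = series$stratum[1])
  class(out) <- "its_fit"
  out
}

#' @export
print.its_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<its_fit> %s / %s stratum, n = %d, R^2 = %.3f\n",
              x$outcome %||% "?", x$stratum %||% "?", x$n, x$r_squared))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Coefficient lookup on an `its_fit`
#' @param fit An `its_fit`.
#' @param term One of `"intercept"`, `"time"`, `"cf_establishment"`,
#'   `"time_since_establishment"`.
#' @return Named numeric vector `estimate`, `se`, `p_value`.
#' @export
its_coef <- function(fit, term) {
  r <- fit$coefficients[fit$coefficients$term == term, ]
  c(estimate = r$estimate, se = r$se, p_value = r$p_value)
}

#' Post-establishment trend regression
#'
#' Simple OLS of the difference series on event time over the
#' post-establishment window `t = 0..t_max`: the intercept is the level of
#' the treated-control gap at establishment, the slope its yearly change.
#' Run per outcome and stratum (the five data sets of the design).
#'
#' @param series Difference series restricted (internally) to `t >= 0`.
#' @return List with `intercept`, `slope`, their SEs and p-values,
#'   `r_squared`, `n` and the `lm` object.
#' @export
fit_post_trend <- function(series) {
  s <- series[series$t >= 0, , drop = FALSE]
  if (nrow(s) < 3) stopf("post-establishment trend needs >= 3 points")
  fit <- lm(D ~ t, data = s)
  sm <- summary(fit)$coefficients
  list(intercept = sm[1, 1], intercept_se = sm[1, 2], intercept_p = sm[1, 4],
       slope = sm[2, 1], slope_se = sm[2, 2], slope_p = sm[2, 4],
       r_squared = summary(fit)$r.squared, n = nrow(s), lm = fit)
}

#' Establishment-year cohort regression
#'
#' OLS of the per-cohort post-establishment difference series on time since
#' establishment, calendar establishment year (uncentered) and their
#' interaction. A negative interaction means later-established cohorts gain
#' less per year — declining conservation effectiveness.
#'
#' @param cohort_panel Data frame from [cohort_difference_panel()] (columns
#'   `est_year`, `t`, `D`).
#' @return A coefficient table (`term`, `estimate`, `se`, `p_value`) plus
#'   `n` and the `lm` fit, as a `cohort_fit` list.
#' @export
fit_cohort_regression <- function(cohort_panel) {
  if (length(unique(cohort_panel$est_year)) < 2)
    stopf("cohort regression needs >= 2 establishment years to identify the interaction")
  fit <- lm(D ~ t * est_year, data = cohort_panel)
  sm <- summary(fit)$coefficients
  ct <- data.frame(term = c("intercept", "t_since_establishment",
                            "establishment_year", "interaction"),
                   estimate = sm[, 1], se = sm[, 2], p_value = sm[, 4])
  rownames(ct) <- NULL
  out <- list(coefficients = ct, n = nrow(cohort_panel), lm = fit)
  class(out) <- "cohort_fit"
  out
}

#' @export
print.cohort_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<cohort_fit> n = %d cohort-year observations\n", x$n))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotonic-trend test: `S` is the sum of signs of all
#' pairwise forward differences, the variance is tie-corrected
#' (`n(n-1)(2n+5)/18 - sum t_k(t_k-1)(2t_k+5)/18`), and the normal
#' approximation uses a continuity correction (`S` shrunk toward 0 by 1).
#'
#' @param x Numeric series (length >= 3).
#' @return List `S`, `tau`, `var_s`, `z`, `p_value` (two-sided).
#' @examples
#' mann_kendall(c(1, 2, 3, 4, 5))$S # 10
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stopf("Mann-Kendall needs at least 3 observations")
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])          # sum over i < j of sign(x_j - x_i)
  ties <- table(x)
  tk <- ties[ties > 1]
  var_s <- n * (n - 1) * (2 * n + 5) / 18 -
    sum(tk * (tk - 1) * (2 * tk + 5)) / 18
  denom <- sqrt(n * (n - 1) / 2 * (n * (n - 1) / 2 - sum(tk * (tk - 1) / 2)))
  tau <- if (denom > 0) S / denom else 0
  z <- if (var_s > 0) {
    if (S > 0) (S - 1) / sqrt(var_s) else if (S < 0) (S + 1) / sqrt(var_s) else 0
  } else 0
  list(S = S, tau = tau, var_s = var_s, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` for a family of `m` tests (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values.
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @examples
#' bonferroni(0.04, m = 9) # 0.36
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stopf("number of tests m must be >= 1")
  p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}
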