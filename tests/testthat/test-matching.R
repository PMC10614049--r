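# SMD, propensity model, greedy matcher, phased matching, balance filter.

test_that("SMD uses the treated-group SD and is signed", {
  expect_equal(compute_smd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_smd(c(1, 2, 3), c(2, 3, 4)), -1)
  tr <- rnorm(200, 10, 2)
  expect_equal(compute_smd(tr, tr + 0.25 * sd(tr)), -0.25, tolerance = 1e-10)
  expect_warning(s <- compute_smd(c(5, 5, 5), c(1, 2)), "undefined")
  expect_true(is.na(s))
  expect_error(compute_smd(1, c(1, 2)), ">= 2 treated")
})

test_that("propensity scores degrade to the marginal under identical covariates", {
  x <- data.frame(a = rnorm(40), b = runif(40))
  p <- fit_propensity(x, x)          # same values in both groups
  expect_true(all(abs(c(p$score_treated, p$score_control) - 0.5) < 1e-6))
  expect_false(p$separation)
  # all-constant covariates: marginal treated fraction
  cst <- data.frame(a = rep(1, 10))
  p2 <- fit_propensity(cst, rbind(cst, cst, cst))
  expect_equal(unique(c(p2$score_treated, p2$score_control)), 0.25)
})

test_that("perfect separation triggers the ridge fallback with monotone scores", {
  tr <- data.frame(a = 10:14 + 0.1)
  co <- data.frame(a = 1:5)
  expect_warning(p <- fit_propensity(tr, co), "separation")
  expect_true(p$separation)
  expect_true(all(p$score_treated > max(p$score_control)))
  expect_true(all(c(p$score_treated, p$score_control) > 0 &
                    c(p$score_treated, p$score_control) < 1))
})

test_that("greedy matching picks nearest scores, hardest treated first", {
  m <- exact_nn_match(data.frame(sample_id = 1, score = 0.6),
                      data.frame(sample_id = 1:2, score = c(0.4, 0.59)))
  expect_equal(m$pairs$control_id, 2)
  expect_equal(m$pairs$score_control, 0.59)
  # higher-score treated processed first, exhausting the pool
  m2 <- exact_nn_match(data.frame(sample_id = 1:2, score = c(0.9, 0.8)),
                       data.frame(sample_id = 9, score = 0.85))
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$treated_id, 1)   # the 0.9 unit got the control
  expect_equal(m2$n_unmatched_treated, 1)
  # exact matching: no cross-stratum pairs
  m3 <- exact_nn_match(
    data.frame(sample_id = 1:2, score = 0.5, stratum = 1),
    data.frame(sample_id = 3:4, score = 0.5, stratum = 0))
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(m3$n_unmatched_treated, 2)
})

test_that("the matcher equals an independent step-by-step oracle", {
  set.seed(77)
  for (rep in 1:200) {
    nt <- sample(1:6, 1); nc <- sample(1:6, 1)
    tr <- data.frame(sample_id = sample(100, nt), score = round(runif(nt), 2),
                     stratum = sample(0:1, nt, replace = TRUE))
    co <- data.frame(sample_id = sample(200:300, nc), score = round(runif(nc), 2),
                     stratum = sample(0:1, nc, replace = TRUE))
    got <- exact_nn_match(tr, co)$pairs
    want <- greedy_match_oracle(tr, co)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$treated_id), ]
      want <- want[order(want$treated_id), ]
      expect_equal(got$treated_id, want$treated_id)
      expect_equal(got$control_id, want$control_id)
    }
  }
})

make_phase_cov <- function(ids, forest, x) {
  data.frame(sample_id = ids, ref_year = 2000, elevation = x, slope = 0.1 * x,
             dist_road = 100 + x, dist_village = 200 + x, dist_district = 300 + x,
             forest_at_est = forest, tcc_at_est = 50 + x,
             dist_nonforest_at_est = abs(x), forest_prop_buffer_at_est = 0.5)
}

test_that("phased matching consumes controls oldest cohort first", {
  samples <- data.frame(sample_id = 1:6,
                        row = 0:5, col = 0,
                        group = c("treated", "treated", rep("control", 4)),
                        est_year = c(2000, 2005, NA, NA, NA, NA))
  # one ideal control (id 3) for both treated units
  cov0 <- make_phase_cov(1:6, 1, c(0, 0, 0.01, 5, 6, 7))
  covs <- list("2000" = cov0, "2005" = cov0)
  suppressWarnings(res <- phased_match(samples, covs))
  p <- res$pairs
  expect_equal(p$control_id[p$phase == 2000], 3)   # earlier phase wins it
  expect_false(3 %in% p$control_id[p$phase == 2005])
  expect_false(anyDuplicated(p$control_id) > 0)
  # pair members share the exact-matching value
  expect_true(all(p$stratum %in% c(0, 1)))
})

test_that("a single phase reduces to plain exact + nearest-neighbor matching", {
  samples <- data.frame(sample_id = 1:8, row = 0:7, col = 1,
                        group = c(rep("treated", 3), rep("control", 5)),
                        est_year = c(rep(2003, 3), rep(NA, 5)))
  cov <- make_phase_cov(1:8, c(1, 1, 0, 1, 1, 0, 0, 1), rnorm(8))
  suppressWarnings(res <- phased_match(samples, list("2003" = cov)))
  expect_true(all(res$pairs$phase == 2003))
  tr_f <- cov$forest_at_est[match(res$pairs$treated_id, cov$sample_id)]
  co_f <- cov$forest_at_est[match(res$pairs$control_id, cov$sample_id)]
  expect_equal(tr_f, co_f)
})

test_that("phase balance filter drops imbalanced phases and reports them", {
  # build a match_result by hand: two phases, one with |SMD| = 0.30
  base <- data.frame(phase = c(2000, 2000, 2001, 2001),
                     when = "post",
                     covariate = "elevation",
                     smd = c(0.10, NA, 0.30, 0.2),
                     defined = c(TRUE, FALSE, TRUE, TRUE),
                     n_treated = 10, n_control = 10)
  pairs <- data.frame(treated_id = 1:4, control_id = 5:8,
                      score_treated = 0.5, score_control = 0.5,
                      stratum = 1, phase = c(2000, 2000, 2001, 2001))
  pc <- data.frame(sample_id = c(1:4, 5:8), ref_year = 2000,
                   elevation = rnorm(8), role = rep(c("treated", "control"), each = 4),
                   phase = rep(c(2000, 2000, 2001, 2001), 2))
  mr <- structure(list(pairs = pairs, balance = base, pair_covariates = pc,
                       covariate_names = "elevation", exact_var = NULL,
                       excluded_phases = integer(0), n_unmatched = integer(0)),
                  class = "match_result")
  out <- filter_balanced_phases(mr, threshold = 0.25)
  expect_equal(out$excluded_phases, 2001)
  expect_true(all(out$pairs$phase == 2000))
  # all phases balanced -> unchanged pair set
  mr2 <- mr; mr2$balance$smd <- c(0.1, NA, 0.2, 0.2)
  out2 <- filter_balanced_phases(mr2, 0.25)
  expect_equal(out2$pairs, pairs)
  # everything imbalanced -> error
  mr3 <- mr; mr3$balance$smd <- c(0.4, NA, 0.4, 0.4)
  expect_error(filter_balanced_phases(mr3, 0.25), "no matched sample")
})

test_that("matching without replacement holds across a full pipeline run", {
  cfg <- tiny_scenario(seed = 41, placement_bias_coefs = c(0.4, 0, -0.4, 0, 0))
  res <- suppressWarnings(run_pipeline(tiny_run(cfg)))
  p <- res$match_raw$pairs
  expect_false(anyDuplicated(p$control_id) > 0)
  expect_false(anyDuplicated(p$treated_id) > 0)
  # exact matching on forest state at the phase year
  for (ph in unique(p$phase)) {
    cov <- res$covariates_by_year[[as.character(ph)]]
    pp <- p[p$phase == ph, ]
    expect_equal(cov$forest_at_est[match(pp$treated_id, cov$sample_id)],
                 cov$forest_at_est[match(pp$control_id, cov$sample_id)])
  }
})
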