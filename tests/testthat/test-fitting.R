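ref_params <- lineup_params(mu_g = 2, c1 = 1, c2 = 1.5, c3 = 2, k = 6)

pred_unif <- function(p7, k = 6) response_distribution(p7, "collapsed", k)

test_that("G-squared is zero for proportional counts and matches hand computation otherwise", {
  p <- c(0.5, 0.3, 0.2, rep(0, 4))
  expect_equal(g_squared(c(50, 30, 20, rep(0, 4)), pred_unif(p)), 0, tolerance = 1e-12)

  # two informative cells: 2 * (60 ln 1.2 + 40 ln 0.8)
  obs <- c(60, 40, rep(0, 5))
  pred <- pred_unif(c(0.5, 0.5, rep(0, 5)))
  expect_equal(g_squared(obs, pred), 4.0271027, tolerance = 1e-6)

  expect_error(g_squared(rep(0, 7), pred), "all-zero")
})

test_that("G-squared applies the 0.001 floor and removes empty cells", {
  # a cell with observations but near-zero predicted probability is floored
  obs <- c(10, 90, rep(0, 5))
  pred <- pred_unif(c(1e-8, 1 - 1e-8, rep(0, 5)))
  expect_equal(g_squared(obs, pred),
               2 * (10 * log(10 / (100 * 0.001)) + 90 * log(90 / (100 * (1 - 1e-8)))),
               tolerance = 1e-8)

  # empty observed cells contribute nothing even where the model puts mass
  obs2 <- c(100, 0, rep(0, 5))
  pred2 <- pred_unif(c(0.8, 0.2, rep(0, 5)))
  expect_equal(g_squared(obs2, pred2), 2 * 100 * log(100 / 80), tolerance = 1e-10)
})

test_that("G-squared is order-invariant and linear in N for fixed proportions", {
  set.seed(41)
  p <- as.numeric(collapsed_probs(ref_params, 0.5))
  obs <- c(12, 19, 33, 15, 9, 5, 107)
  pred <- pred_unif(p)
  perm <- sample(7)
  expect_equal(g_squared(obs[perm], pred_unif(p[perm])), g_squared(obs, pred),
               tolerance = 1e-12)
  expect_equal(g_squared(10 * obs, pred), 10 * g_squared(obs, pred),
               tolerance = 1e-9)
})

test_that("the fit recovers generating parameters from near-asymptotic counts", {
  probs <- as.numeric(collapsed_probs(ref_params, 0.5))
  N <- 1e6
  cnt <- round(N * probs)
  cnt[7] <- cnt[7] + (N - sum(cnt))
  counts <- collapsed_counts(6, cnt)
  fit <- fit_collapsed(counts, n_restarts = 0)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["p_g"]] - 0.5), 0.01)
  expect_lt(abs(fit$estimates[["mu_g"]] - 2), 0.05)
  expect_lt(abs(fit$estimates[["c1"]] - 1), 0.05)
  expect_false(any(fit$boundary))
  expect_identical(fit$df, 6L)

  # fixing the base rate at the free optimum reproduces the optimum
  fx <- fit_collapsed(counts, fixed_pg = fit$estimates[["p_g"]], n_restarts = 0)
  expect_lt(abs(fx$g_squared - fit$g_squared), 1e-6)
  expect_identical(fx$fixed_pg, fit$estimates[["p_g"]])
})

test_that("multi-size weighting reduces to the single-size statistic when all trials share one size", {
  tr <- simulate_trials(sim_config(ref_params, 0.5, 800, seed = 51))
  counts <- collapse_table(tr)
  f1 <- fit_collapsed(counts, n_restarts = 0)
  theta <- c(mu_g = 2.1, c1 = 0.9, dc2 = 0.55, dc3 = 0.45, p_g = 0.48)
  expect_equal(lineupSDT:::.weighted_g2(theta, counts, 0.001),
               g_squared(lineupSDT:::count_matrix(counts)[1, ],
                         collapsed_probs(lineup_params(2.1, 0.9, 1.45, 1.9, k = 6), 0.48)),
               tolerance = 1e-10)
  expect_true(is.finite(f1$g_squared))
})

test_that("fits pool information across lineup sizes by trial proportion", {
  set.seed(61)
  t6 <- simulate_trials(sim_config(ref_params, 0.45, 700))
  t8 <- simulate_trials(sim_config(lineup_params(2, 1, 1.5, 2, k = 8), 0.45, 300))
  t8$trial <- t8$trial + 700
  both <- rbind(t6, t8)
  class(both) <- c("trial_table", "data.frame")
  counts <- collapse_table(both)
  expect_identical(counts$k, c(6L, 8L))
  expect_identical(counts$n, c(700L, 300L))
  fit <- fit_collapsed(counts, n_restarts = 0)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["p_g"]] - 0.45), 0.15)
})

test_that("invalid fixed base rates are rejected", {
  counts <- collapse_table(simulate_trials(sim_config(ref_params, 0.5, 300, seed = 1)))
  expect_error(fit_collapsed(counts, fixed_pg = 0), "strictly inside")
  expect_error(fit_collapsed(counts, fixed_pg = 1.2), "strictly inside")
})

test_that("the sensitivity profile is parabolic around the generating base rate", {
  tr <- simulate_trials(sim_config(ref_params, 0.5, 1000, seed = 31))
  counts <- collapse_table(tr)
  prof <- sensitivity_profile(counts, grid = seq(0.05, 0.95, by = 0.05),
                              reference_pg = 0.5)
  g <- prof$profile
  expect_lt(abs(prof$best_pg - 0.5), 0.1)
  expect_true(all(prof$g2_min <= g$g_squared + 1e-9))
  # fits at implausible base rates are much worse than the minimum
  expect_gt(g$g_squared[g$p_g == 0.05] - prof$g2_min, 3.84)
  expect_gt(g$g_squared[g$p_g == 0.95] - prof$g2_min, 3.84)
  expect_gte(prof$lr, 1)

  # reference at the profile argmin gives lr = 1
  prof2 <- sensitivity_profile(counts, grid = seq(0.05, 0.95, by = 0.05),
                               reference_pg = prof$best_pg)
  expect_equal(prof2$lr, 1, tolerance = 1e-6)
})

test_that("the profile at the free-fit optimum reproduces the free fit's statistic", {
  counts <- collapse_table(simulate_trials(sim_config(ref_params, 0.5, 1000, seed = 71)))
  free <- fit_collapsed(counts, n_restarts = 0)
  refit <- lineupSDT:::.refit_from(counts, free, free$estimates[["p_g"]],
                                   0.001, 5, 5000)
  expect_lt(abs(refit$g_squared - free$g_squared), 1e-6)
})

test_that("the parametric bootstrap is seed-reproducible and concentrates near the generating base rate", {
  counts <- collapse_table(simulate_trials(sim_config(ref_params, 0.5, 1000, seed = 91)))
  fit <- fit_collapsed(counts, n_restarts = 0)

  one_a <- parametric_bootstrap(fit, fixed_pg = 0.5, n_reps = 1, n = 500, seed = 7)
  one_b <- parametric_bootstrap(fit, fixed_pg = 0.5, n_reps = 1, n = 500, seed = 7)
  expect_identical(one_a, one_b)

  big <- parametric_bootstrap(fit, fixed_pg = 0.5, n_reps = 100, n = 1000, seed = 8)
  expect_identical(nrow(big), 100L)
  expect_lt(abs(median(big$p_g, na.rm = TRUE) - 0.5), 0.05)
  expect_true(all(big$p_g >= 0.001 & big$p_g <= 0.999, na.rm = TRUE))

  # sampling variability shrinks with sample size
  small <- parametric_bootstrap(fit, fixed_pg = 0.5, n_reps = 100, n = 100, seed = 8)
  expect_gt(IQR(small$p_g, na.rm = TRUE), IQR(big$p_g, na.rm = TRUE))
})
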