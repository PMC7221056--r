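ref_params <- lineup_params(mu_g = 2, c1 = 1, c2 = 1.5, c3 = 2, k = 6)

make_table <- function(lineup_type, response, confidence) {
  tab <- data.frame(trial = seq_along(response), k = 6L,
                    lineup_type = lineup_type, response = response,
                    confidence = confidence, stringsAsFactors = FALSE)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

test_that("trial-level calibration computes accuracy and suspect share from counts", {
  # 10 low-confidence suspect picks, 6 to guilty suspects -> accuracy 0.60
  tab <- make_table(
    lineup_type = c(rep("guilty", 6), rep("innocent", 4), rep("innocent", 7),
                    rep("guilty", 2), rep("innocent", 3)),
    response = c(rep("suspect", 10), rep("filler", 7), rep("reject", 5)),
    confidence = c(rep("low", 17), rep(NA, 5)))
  cal <- calibration_from_trials(tab)
  low <- cal[cal$level == "low", ]
  expect_equal(low$accuracy, 0.60)
  expect_identical(low$n_accuracy, 10L)
  # 17 low-confidence identifications, 10 of them suspect picks
  expect_equal(low$suspect_share, 10 / 17)
  # 3 of 5 rejections had an innocent suspect
  expect_equal(cal[cal$level == "reject", "accuracy"], 0.6)

  # a 30% suspect share arises from 3 suspect vs 7 filler picks
  tab2 <- make_table(rep("guilty", 10), c(rep("suspect", 3), rep("filler", 7)),
                     rep("low", 10))
  expect_equal(calibration_from_trials(tab2)[1, "suspect_share"], 0.30)
  # every suspect pick guilty -> accuracy 1
  expect_equal(calibration_from_trials(tab2)[1, "accuracy"], 1)

  # empty cells are flagged NA with zero denominator, never zero accuracy
  expect_true(is.na(calibration_from_trials(tab2)[2, "accuracy"]))
  expect_identical(calibration_from_trials(tab2)[2, "n_accuracy"], 0L)
})

test_that("model calibration has the right boundary behaviour", {
  cal0 <- calibration_from_model(ref_params, p_g = 0)
  expect_equal(cal0$accuracy[1:3], rep(0, 3))
  expect_equal(cal0$accuracy[4], 1)

  cal1 <- calibration_from_model(ref_params, p_g = 1)
  expect_equal(cal1$accuracy[1:3], rep(1, 3))
  expect_equal(cal1$accuracy[4], 0)
})

test_that("model calibration matches empirical calibration of data simulated at the same parameters", {
  p_g <- 0.4
  tab <- simulate_trials(sim_config(ref_params, p_g, 1e6, seed = 303))
  emp <- calibration_from_trials(tab)
  mod <- calibration_from_model(ref_params, p_g = p_g)
  expect_equal(emp$accuracy, mod$accuracy, tolerance = 0.01)
  expect_equal(emp$suspect_share[1:3], mod$suspect_share[1:3], tolerance = 0.01)
})

test_that("model calibration accuracy per bin equals the per-bin posterior probability of guilt", {
  p_g <- 0.35
  mod <- calibration_from_model(ref_params, p_g = p_g)
  g <- category_probs_guilty(ref_params)
  i <- category_probs_innocent(ref_params)
  for (b in 1:3) {
    expect_equal(mod$accuracy[b], ppg(p_g, g[[b]], i[[b]])$ppg, tolerance = 1e-12)
  }
})

test_that("the matched-increase contrast separates the memory and base-rate routes", {
  base_pg <- 0.35
  susp_cols <- 1:3

  null_case <- confidence_profile_contrast(ref_params, base_pg, delta = 0)
  expect_equal(as.numeric(null_case$mu_route), as.numeric(null_case$baseline))
  expect_equal(as.numeric(null_case$pg_route), as.numeric(null_case$baseline))

  ctr <- confidence_profile_contrast(ref_params, base_pg, delta = 0.05)
  mass <- function(d) sum(as.numeric(d)[susp_cols])
  # both routes hit the same total collapsed suspect-ID mass
  expect_lt(abs(mass(ctr$mu_route) - mass(ctr$pg_route)), 1e-6)
  expect_lt(abs(mass(ctr$mu_route) - (mass(ctr$baseline) + 0.05)), 1e-6)

  base <- as.numeric(ctr$baseline)
  mu_r <- as.numeric(ctr$mu_route)
  pg_r <- as.numeric(ctr$pg_route)

  # memory route concentrates the gain at high confidence...
  expect_gt(mu_r[3], pg_r[3])
  # ...at the cost of low/medium-confidence suspect picks
  expect_lt(mu_r[1], pg_r[1])
  expect_lt(mu_r[2], pg_r[2])

  # the base-rate route never decreases any suspect confidence category
  expect_true(all(pg_r[susp_cols] >= base[susp_cols] - 1e-12))

  # filler confidence profiles differ between routes far less than suspect profiles
  fill_diff <- max(abs(mu_r[4:6] - pg_r[4:6]))
  susp_diff <- max(abs(mu_r[susp_cols] - pg_r[susp_cols]))
  expect_lt(fill_diff, susp_diff)

  expect_error(confidence_profile_contrast(ref_params, base_pg, delta = 0.9),
               "not attainable")
})

test_that("the bootstrap base-rate study recovers a matched base rate and is reproducible", {
  src <- simulate_trials(sim_config(ref_params, 0.5, 4000, seed = 77))
  study <- bootstrap_base_rate_study(src, base_rates = 0.5, n_reps = 25,
                                     n = 1000, seed = 5)
  expect_identical(nrow(study$estimates), 25L)
  expect_lt(abs(study$summary$median - 0.5), 0.05)
  expect_true(all(study$estimates$p_g >= 0.001 & study$estimates$p_g <= 0.999))
  expect_true(all(c("ppg_low", "ppg_medium", "ppg_high") %in% names(study$estimates)))
  expect_true(study$summary$q10 <= study$summary$median &
                study$summary$median <= study$summary$q90)

  again <- bootstrap_base_rate_study(src, base_rates = 0.5, n_reps = 1,
                                     n = 1000, seed = 9)
  again2 <- bootstrap_base_rate_study(src, base_rates = 0.5, n_reps = 1,
                                      n = 1000, seed = 9)
  expect_identical(again$estimates, again2$estimates)
})

test_that("recovery studies record generating and recovered parameters with diagnostics", {
  study <- parameter_recovery_study(n_replicates = 8, N_values = 500, seed = 3)
  expect_identical(nrow(study), 8L)
  expect_true(all(c("true_p_g", "est_p_g", "true_ppg_high", "est_ppg_high",
                    "g_squared", "converged", "mu_g_at_cap") %in% names(study)))
  expect_true(all(study$est_p_g >= 0.001 & study$est_p_g <= 0.999, na.rm = TRUE))
  expect_true(all(study$est_mu_g <= 5 + 1e-9, na.rm = TRUE))
  # study is reproducible under the master seed
  study2 <- parameter_recovery_study(n_replicates = 8, N_values = 500, seed = 3)
  expect_identical(study, study2)

  # sigma_g = 1 misspecification study reduces to the standard engine
  uv1 <- uv_misspecification_study(sigma_g_true = 1, n_replicates = 3,
                                   N = 400, seed = 11)
  std <- parameter_recovery_study(n_replicates = 3, N_values = 400, seed = 11)
  expect_equal(uv1$est_p_g, std$est_p_g, tolerance = 1e-12)
  expect_true(all(uv1$true_sigma_g == 1))
})
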