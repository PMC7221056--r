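#' Bootstrap base-rate recovery study
#'
#' Evaluates base-rate estimation on resampled data sets with controlled
#' base rates. For each target base rate, `n_reps` bootstrap data sets of
#' `n` trials are built from a labeled source table with [bootstrap_mix()],
#' collapsed, and fit with the base rate free; the estimated base rate and
#' model PPG per confidence level are recorded for every replicate.
#'
#' @param labeled A `"trial_table"` with both lineup types.
#' @param base_rates Target base rates (default `c(0.20, 0.35, 0.50, 0.65,
#'   0.80)`, covering the plausible range for police lineups).
#' @param n_reps Replicates per base rate (default 1000).
#' @param n Trials per bootstrap data set (default 1000).
#' @param seed Integer master seed.
#' @param n_restarts Restarts per fit (default 0: fixed-start protocol).
#' @return A list of class `"base_rate_study"` with `estimates` (one row
#'   per base rate x replicate: `base_rate`, `rep`, `p_g`, `g_squared`,
#'   `converged`, `mu_g_at_cap`, `ppg_low/medium/high`) and `summary`
#'   (median and 10th/90th quantiles of the estimated base rate per
#'   condition).
#' @export
bootstrap_base_rate_study <- function(labeled,
                                      base_rates = c(0.20, 0.35, 0.50, 0.65, 0.80),
                                      n_reps = 1000, n = 1000, seed = 1,
                                      n_restarts = 0) {
  stopifnot(inherits(labeled, "trial_table"), n_reps >= 1)
  set.seed(seed)
  rows <- vector("list", length(base_rates) * n_reps)
  idx <- 0L
  for (br in base_rates) {
    for (r in seq_len(n_reps)) {
      idx <- idx + 1L
      mixed <- bootstrap_mix(labeled, br, n = n)
      rows[[idx]] <- tryCatch({
        fit <- fit_collapsed(collapse_table(mixed), n_restarts = n_restarts)
        ppgc <- .ppg_by_confidence(fitted_params(fit), fit$estimates[["p_g"]])
        data.frame(base_rate = br, rep = r,
                   p_g = fit$estimates[["p_g"]], g_squared = fit$g_squared,
                   converged = fit$converged,
                   mu_g_at_cap = fit$boundary[["mu_g_at_cap"]],
                   ppg_low = ppgc[["low"]], ppg_medium = ppgc[["medium"]],
                   ppg_high = ppgc[["high"]])
      }, error = function(e) {
        data.frame(base_rate = br, rep = r, p_g = NA_real_,
                   g_squared = NA_real_, converged = FALSE, mu_g_at_cap = NA,
                   ppg_low = NA_real_, ppg_medium = NA_real_,
                   ppg_high = NA_real_)
      })
    }
  }
  estimates <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(estimates, estimates$base_rate), function(d) {
    q <- stats::quantile(d$p_g, c(0.1, 0.5, 0.9), na.rm = TRUE, type = 7)
    data.frame(base_rate = d$base_rate[1], n_reps = nrow(d),
               q10 = q[[1]], median = q[[2]], q90 = q[[3]],
               n_failed = sum(!d$converged | is.na(d$p_g)))
  }))
  rownames(summ) <- NULL
  structure(list(estimates = estimates, summary = summ, n = n, seed = seed),
            class = "base_rate_study")
}

#' @export
print.base_rate_study <- function(x, ...) {
  cat(sprintf("Bootstrap base-rate study (%d trials per data set)\n", x$n))
  print.data.frame(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

## Shared engine for recovery / misspecification studies: sample a random
## generating configuration, simulate, fit the equal-variance model, record
## generating vs recovered parameters and analytic PPG per confidence level.
.recovery_engine <- function(n_replicates, N_values, seed, sigma_g, k,
                             n_restarts) {
  set.seed(seed)
  rows <- vector("list", n_replicates * length(N_values))
  idx <- 0L
  for (N in N_values) {
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      cfg <- sample_random_params(n = N, k = k, sigma_g = sigma_g)
      gen <- cfg$params
      ppg_true <- .ppg_by_confidence(gen, cfg$p_g)
      base <- data.frame(
        N = N, rep = r,
        true_mu_g = gen$mu_g, true_c1 = gen$c1, true_c2 = gen$c2,
        true_c3 = gen$c3, true_p_g = cfg$p_g, true_sigma_g = sigma_g,
        true_ppg_low = ppg_true[["low"]], true_ppg_medium = ppg_true[["medium"]],
        true_ppg_high = ppg_true[["high"]])
      rows[[idx]] <- tryCatch({
        trials <- simulate_trials(cfg)
        fit <- fit_collapsed(collapse_table(trials), n_restarts = n_restarts)
        e <- fit$estimates
        ppg_est <- .ppg_by_confidence(fitted_params(fit), e[["p_g"]])
        cbind(base, data.frame(
          est_mu_g = e[["mu_g"]], est_c1 = e[["c1"]], est_c2 = e[["c2"]],
          est_c3 = e[["c3"]], est_p_g = e[["p_g"]],
          g_squared = fit$g_squared, converged = fit$converged,
          mu_g_at_cap = fit$boundary[["mu_g_at_cap"]],
          est_ppg_low = ppg_est[["low"]], est_ppg_medium = ppg_est[["medium"]],
          est_ppg_high = ppg_est[["high"]]))
      }, error = function(e2) {
        cbind(base, data.frame(
          est_mu_g = NA_real_, est_c1 = NA_real_, est_c2 = NA_real_,
          est_c3 = NA_real_, est_p_g = NA_real_, g_squared = NA_real_,
          converged = FALSE, mu_g_at_cap = NA,
          est_ppg_low = NA_real_, est_ppg_medium = NA_real_,
          est_ppg_high = NA_real_))
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("recovery_study", "data.frame")
  out
}

#' Parameter-recovery simulation study
#'
#' The full sample-simulate-fit-record loop: for each replicate a generating
#' parameter set is drawn from the study's uniform ranges
#' (see [sample_random_params()]), a data set of `N` identification attempts
#' is simulated under the max rule, and the equal-variance model is fit to
#' the collapsed counts with the base rate free, always starting from the
#' same fixed initial values. Generating and recovered parameters, fit
#' diagnostics, and actual vs estimated PPG per confidence level are
#' recorded per replicate. Actual PPG is computed analytically from the
#' generating parameters.
#'
#' @param n_replicates Replicates per sample size (default 250).
#' @param N_values Sample sizes to study (default `c(100, 500, 1000)`).
#' @param seed Integer master seed.
#' @param k Lineup size (default 6).
#' @param n_restarts Restarts per fit (default 0: fixed-start protocol).
#' @return A `"recovery_study"` data frame, one row per replicate, with
#'   `true_*` and `est_*` parameter columns, `g_squared`, `converged`,
#'   `mu_g_at_cap`, and `true_ppg_*` / `est_ppg_*` per confidence level.
#' @export
parameter_recovery_study <- function(n_replicates = 250,
                                     N_values = c(100, 500, 1000),
                                     seed = 1, k = 6, n_restarts = 0) {
  stopifnot(n_replicates >= 1, all(N_values >= 1))
  .recovery_engine(n_replicates, N_values, seed, sigma_g = 1, k = k,
                   n_restarts = n_restarts)
}

#' Unequal-variance misspecification study
#'
#' Robustness check: data are generated from an unequal-variance model
#' (target SD `sigma_g_true`, default 1.5 — 50% larger than the lure SD)
#' but fit with the equal-variance model. Individual parameter estimates
#' are biased in this regime (base rate low, memory strength high), yet the
#' biases largely cancel in the posterior probability of guilt; the
#' returned table lets both effects be measured.
#'
#' @param sigma_g_true Generating target-distribution SD (default 1.5).
#' @param n_replicates Number of replicates (default 100).
#' @param N Identification attempts per data set (default 1000).
#' @inheritParams parameter_recovery_study
#' @return A `"recovery_study"` data frame as in
#'   [parameter_recovery_study()].
#' @export
uv_misspecification_study <- function(sigma_g_true = 1.5, n_replicates = 100,
                                      N = 1000, seed = 1, k = 6,
                                      n_restarts = 0) {
  stopifnot(sigma_g_true > 0)
  .recovery_engine(n_replicates, N, seed, sigma_g = sigma_g_true, k = k,
                   n_restarts = n_restarts)
}

#' Matched-increase contrast: memory strength versus base rate
#'
#' Two different mechanisms can raise the overall rate of suspect
#' identifications in collapsed data: stronger witness memory (larger
#' `mu_g`) or a higher base rate of guilty suspects (larger `p_g`). This
#' contrast solves for the `mu_g` increment and the `p_g` increment that
#' each raise the total collapsed suspect-identification probability by the
#' same amount `delta`, and returns the two perturbed collapsed
#' distributions alongside the baseline. The confidence profiles differ
#' diagnostically: the memory route concentrates the extra suspect
#' identifications at high confidence, while the base-rate route raises all
#' confidence levels without decreasing any.
#'
#' @param params Baseline [lineup_params()].
#' @param p_g Baseline base rate.
#' @param delta Required increase in total collapsed suspect-ID probability.
#' @param tol Root-finding tolerance on the matched mass (default 1e-8).
#' @return A list of class `"profile_contrast"`: `baseline`, `mu_route`,
#'   `pg_route` (collapsed [response_distribution()]s), `mu_g_new`,
#'   `p_g_new`, `delta`, `target_mass`.
#' @export
confidence_profile_contrast <- function(params, p_g, delta, tol = 1e-8) {
  params <- as_lineup_params(params)
  stopifnot(p_g >= 0, p_g <= 1, delta >= 0)
  susp <- paste0("suspect_", CONFIDENCE_LEVELS)
  susp_mass <- function(mu, pg) {
    pars <- lineup_params(mu, params$c1, params$c2, params$c3, k = params$k,
                          sigma_g = params$sigma_g)
    sum(unclass(collapsed_probs(pars, pg))[susp])
  }
  base_mass <- susp_mass(params$mu_g, p_g)
  target <- base_mass + delta
  baseline <- collapsed_probs(params, p_g)
  if (delta == 0) {
    return(structure(list(baseline = baseline, mu_route = baseline,
                          pg_route = baseline, mu_g_new = params$mu_g,
                          p_g_new = p_g, delta = 0, target_mass = base_mass),
                     class = "profile_contrast"))
  }

  ## p_g route: collapsed suspect mass is linear in p_g
  g_mass <- sum(unclass(category_probs_guilty(params))[susp])
  i_mass <- sum(unclass(category_probs_innocent(params))[susp])
  if (abs(g_mass - i_mass) < 1e-12 || target > max(g_mass, i_mass) + 1e-12) {
    stop("target suspect-ID increase is not attainable by raising the base rate")
  }
  p_g_new <- (target - i_mass) / (g_mass - i_mass)
  if (p_g_new < 0 || p_g_new > 1) {
    stop("target suspect-ID increase is not attainable by raising the base rate")
  }

  ## mu_g route: suspect mass is increasing in mu_g; bracket then root-find
  upper <- params$mu_g + 1
  while (susp_mass(upper, p_g) < target && upper < params$mu_g + 50) {
    upper <- upper + 1
  }
  if (susp_mass(upper, p_g) < target) {
    stop("target suspect-ID increase is not attainable by raising mu_g")
  }
  mu_g_new <- stats::uniroot(function(m) susp_mass(m, p_g) - target,
                             c(params$mu_g, upper), tol = tol)$root

  mu_params <- lineup_params(mu_g_new, params$c1, params$c2, params$c3,
                             k = params$k, sigma_g = params$sigma_g)
  structure(
    list(baseline = baseline,
         mu_route = collapsed_probs(mu_params, p_g),
         pg_route = collapsed_probs(params, p_g_new),
         mu_g_new = mu_g_new, p_g_new = p_g_new,
         delta = delta, target_mass = target),
    class = "profile_contrast"
  )
}

#' @export
print.profile_contrast <- function(x, digits = 4, ...) {
  cat("Matched suspect-ID increase: memory-strength vs base-rate route\n")
  cat(sprintf("  target collapsed suspect-ID mass: %.4f (delta = %.4f)\n",
              x$target_mass, x$delta))
  cat(sprintf("  mu_g route: mu_g -> %.4f;  p_g route: p_g -> %.4f\n",
              x$mu_g_new, x$p_g_new))
  m <- rbind(baseline = unclass(x$baseline), mu_route = unclass(x$mu_route),
             pg_route = unclass(x$pg_route))
  print(round(m, digits))
  invisible(x)
}
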