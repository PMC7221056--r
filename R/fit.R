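## Parameter vector layout for fitting: (mu_g, c1, dc2, dc3, p_g), with the
## criteria optimized as c1 and positive gaps so the ordering c1 < c2 < c3
## is structural. Box bounds; the mu_g cap mirrors the estimation ceiling
## used when fits run away (estimates landing on it are flagged, not hidden).
.fit_bounds <- function(mu_cap = 5) {
  list(lower = c(mu_g = 0, c1 = -3, dc2 = 1e-4, dc3 = 1e-4, p_g = 0.001),
       upper = c(mu_g = mu_cap, c1 = 5, dc2 = 5, dc3 = 5, p_g = 0.999))
}

.theta_start <- c(mu_g = 2, c1 = 1, dc2 = 0.5, dc3 = 0.5, p_g = 0.5)

.theta_to_params <- function(theta, k) {
  lineup_params(mu_g = theta[["mu_g"]], c1 = theta[["c1"]],
                c2 = theta[["c1"]] + theta[["dc2"]],
                c3 = theta[["c1"]] + theta[["dc2"]] + theta[["dc3"]],
                k = k)
}

## Trial-proportion-weighted G^2 across lineup sizes for one parameter set.
.weighted_g2 <- function(theta, counts, floor) {
  obs <- count_matrix(counts)
  w <- counts$n / sum(counts$n)
  c1 <- theta[["c1"]]
  c2 <- c1 + theta[["dc2"]]
  c3 <- c2 + theta[["dc3"]]
  total <- 0
  for (i in seq_len(nrow(counts))) {
    pred <- .collapsed_probs_fast(theta[["mu_g"]], c1, c2, c3,
                                  counts$k[i], theta[["p_g"]])
    o <- obs[i, ]
    p <- pmax(pred, floor)
    keep <- o > 0
    g2 <- 2 * sum(o[keep] * log(o[keep] / (counts$n[i] * p[keep])))
    total <- total + w[i] * g2
  }
  total
}

#' Fit the lineup SDT model to collapsed counts
#'
#' Estimates the equal-variance max-rule model — memory strength `mu_g`,
#' confidence criteria `c1 < c2 < c3`, and the base rate of guilty suspects
#' `p_g` — from collapsed 7-category identification counts by minimizing the
#' G-squared statistic. When counts for several lineup sizes are supplied,
#' the same parameters predict each size and the per-size statistics are
#' combined weighted by the proportion of trials at each size.
#'
#' Optimization is a bounded derivative-free Nelder-Mead search from the
#' fixed starting point `mu_g = 2`, `c = (1, 1.5, 2)`, `p_g = 0.5`, with
#' optional jittered restarts to guard against local minima. `mu_g` is
#' capped (default 5); estimates landing on the cap or on the `p_g` bounds
#' are flagged rather than silently accepted.
#'
#' @param counts A [collapsed_counts()] object (one row per lineup size).
#' @param fixed_pg Optional base rate in (0, 1) at which `p_g` is held fixed
#'   while the remaining four parameters are optimized.
#' @param floor Lower bound on predicted cell probabilities in the fit
#'   statistic (default 0.001).
#' @param mu_cap Upper bound on `mu_g` (default 5).
#' @param n_restarts Number of additional jittered restarts (default 5; use
#'   0 to reproduce a single fixed-start protocol).
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @return An object of class `"lineup_fit"`: a list with `estimates`
#'   (named vector `mu_g`, `c1`, `c2`, `c3`, `p_g`), `g_squared`,
#'   `converged`, `boundary` (logical flags `mu_g_at_cap`, `p_g_at_bound`),
#'   `iterations`, `fixed_pg`, `df` (collapsed data degrees of freedom),
#'   and the input `counts`.
#' @seealso [sensitivity_profile()], [parametric_bootstrap()]
#' @export
fit_collapsed <- function(counts, fixed_pg = NULL, floor = 0.001, mu_cap = 5,
                          n_restarts = 5, maxit = 5000) {
  stopifnot(inherits(counts, "collapsed_counts"))
  if (!is.null(fixed_pg) &&
      (!is.finite(fixed_pg) || fixed_pg <= 0 || fixed_pg >= 1)) {
    stop("fixed_pg must lie strictly inside (0, 1)")
  }
  b <- .fit_bounds(mu_cap)
  free <- if (is.null(fixed_pg)) names(.theta_start) else setdiff(names(.theta_start), "p_g")

  project <- function(theta) pmin(pmax(theta, b$lower[names(theta)]), b$upper[names(theta)])
  objective <- function(x) {
    theta <- .theta_start
    theta[free] <- x
    if (!is.null(fixed_pg)) theta[["p_g"]] <- fixed_pg
    proj <- project(theta)
    ## quadratic pull-back keeps the simplex from drifting outside the box
    .weighted_g2(proj, counts, floor) + 1e3 * sum((theta - proj)^2)
  }

  starts <- list(.theta_start[free])
  if (n_restarts > 0) {
    ## deterministic jitter; does not disturb the caller's RNG stream
    seed_state <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(seed_state)) assign(".Random.seed", seed_state, envir = globalenv()),
            add = TRUE)
    set.seed(20260101L)
    jitter_sd <- c(mu_g = 0.75, c1 = 0.4, dc2 = 0.15, dc3 = 0.15, p_g = 0.2)[free]
    for (r in seq_len(n_restarts)) {
      s <- .theta_start[free] + stats::rnorm(length(free), 0, jitter_sd)
      names(s) <- free
      s <- pmin(pmax(s, b$lower[free] + 1e-3), b$upper[free] - 1e-3)
      starts[[r + 1L]] <- s
    }
  }

  best <- NULL
  total_iter <- 0L
  for (s in starts) {
    res <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    total_iter <- total_iter + res$counts[["function"]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  ## polish pass: a fresh simplex at the solution; stationarity there counts
  ## as convergence even when the first simplex ended degenerate
  polish <- stats::optim(best$par, objective, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
  total_iter <- total_iter + polish$counts[["function"]]
  improvement <- best$value - polish$value
  converged <- polish$convergence == 0L || best$convergence == 0L ||
    improvement < 1e-8
  if (polish$value < best$value) best <- polish

  theta <- .theta_start
  theta[free] <- best$par
  if (!is.null(fixed_pg)) theta[["p_g"]] <- fixed_pg
  theta <- project(theta)
  est <- c(mu_g = theta[["mu_g"]], c1 = theta[["c1"]],
           c2 = theta[["c1"]] + theta[["dc2"]],
           c3 = theta[["c1"]] + theta[["dc2"]] + theta[["dc3"]],
           p_g = theta[["p_g"]])

  structure(
    list(estimates = est,
         g_squared = .weighted_g2(theta, counts, floor),
         converged = converged,
         boundary = c(
           mu_g_at_cap = est[["mu_g"]] >= mu_cap - 1e-6,
           p_g_at_bound = is.null(fixed_pg) &&
             (est[["p_g"]] <= b$lower[["p_g"]] + 1e-6 ||
              est[["p_g"]] >= b$upper[["p_g"]] - 1e-6)),
         iterations = total_iter,
         fixed_pg = fixed_pg,
         floor = floor,
         mu_cap = mu_cap,
         df = lineup_df(collapsed = TRUE),
         counts = counts),
    class = "lineup_fit"
  )
}

#' @export
print.lineup_fit <- function(x, ...) {
  cat("Lineup SDT model fit (collapsed data, equal variance)\n")
  cat(sprintf("  mu_g = %.3f  c = (%.3f, %.3f, %.3f)  p_g = %.3f%s\n",
              x$estimates[["mu_g"]], x$estimates[["c1"]], x$estimates[["c2"]],
              x$estimates[["c3"]], x$estimates[["p_g"]],
              if (!is.null(x$fixed_pg)) " [fixed]" else ""))
  cat(sprintf("  G^2 = %.4f on data with %d df; converged: %s\n",
              x$g_squared, x$df, x$converged))
  if (any(x$boundary)) {
    cat("  boundary flags:", paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Model-implied parameters of a fit
#'
#' @param fit A `"lineup_fit"` object.
#' @param k Lineup size for which to build the parameter object (defaults to
#'   the first size in the fitted counts).
#' @return A [lineup_params()] object at the fitted estimates.
#' @export
fitted_params <- function(fit, k = NULL) {
  stopifnot(inherits(fit, "lineup_fit"))
  if (is.null(k)) k <- fit$counts$k[1]
  e <- fit$estimates
  lineup_params(mu_g = e[["mu_g"]], c1 = e[["c1"]], c2 = e[["c2"]],
                c3 = e[["c3"]], k = k)
}

#' Base-rate sensitivity profile
#'
#' Refits the model many times with the base-rate parameter held at each
#' value of a grid (nuisance parameters re-optimized at every point), to
#' check whether the data actually constrain the estimated base rate: a
#' well-identified base rate shows a parabolic G-squared profile with a
#' clear minimum near the estimate, while a flat profile means the estimate
#' should not be trusted.
#'
#' The relative likelihood of the best-fitting base rate against a reference
#' value (for example, a known experimental base rate) is
#' `lr = exp((G2(reference) - G2(best)) / 2)`.
#'
#' @inheritParams fit_collapsed
#' @param grid Base-rate grid, default `seq(0.01, 0.99, by = 0.01)`.
#' @param reference_pg Reference base rate for the relative likelihood.
#' @param n_restarts Jittered restarts per grid point (default 0; each point
#'   is also warm-started from its neighbour's solution).
#' @return An object of class `"sensitivity_profile"`: list with `profile`
#'   (data frame of `p_g`, `g_squared`, `converged`), `best_pg`, `g2_min`,
#'   `reference_pg`, `g2_reference`, `lr`.
#' @export
sensitivity_profile <- function(counts, grid = seq(0.01, 0.99, by = 0.01),
                                reference_pg = 0.5, floor = 0.001, mu_cap = 5,
                                n_restarts = 0, maxit = 5000) {
  stopifnot(all(grid > 0 & grid < 1), reference_pg > 0, reference_pg < 1)
  grid <- sort(grid)
  fit_at <- function(pg) fit_collapsed(counts, fixed_pg = pg, floor = floor,
                                       mu_cap = mu_cap, n_restarts = n_restarts,
                                       maxit = maxit)
  g2 <- numeric(length(grid))
  conv <- logical(length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    f <- fit_at(grid[i])
    ## warm start: re-fit from the neighbouring solution and keep the better
    if (!is.null(prev)) {
      warm <- .refit_from(counts, prev, grid[i], floor, mu_cap, maxit)
      if (warm$g_squared < f$g_squared) f <- warm
    }
    g2[i] <- f$g_squared
    conv[i] <- f$converged
    prev <- f
  }
  i_min <- which.min(g2)
  g2_ref <- if (any(abs(grid - reference_pg) < 1e-12)) {
    g2[which.min(abs(grid - reference_pg))]
  } else {
    fit_at(reference_pg)$g_squared
  }
  structure(
    list(profile = data.frame(p_g = grid, g_squared = g2, converged = conv),
         best_pg = grid[i_min], g2_min = g2[i_min],
         reference_pg = reference_pg, g2_reference = g2_ref,
         lr = exp(max(g2_ref - g2[i_min], 0) / 2)),
    class = "sensitivity_profile"
  )
}

## One Nelder-Mead pass with p_g fixed, started from an existing fit.
.refit_from <- function(counts, fit, pg, floor, mu_cap, maxit) {
  b <- .fit_bounds(mu_cap)
  e <- fit$estimates
  start <- c(mu_g = e[["mu_g"]], c1 = e[["c1"]],
             dc2 = max(e[["c2"]] - e[["c1"]], 1e-4),
             dc3 = max(e[["c3"]] - e[["c2"]], 1e-4))
  start <- pmin(pmax(start, b$lower[names(start)] + 1e-6),
                b$upper[names(start)] - 1e-6)
  objective <- function(x) {
    theta <- c(x, p_g = pg)
    proj <- pmin(pmax(theta, b$lower[names(theta)]), b$upper[names(theta)])
    .weighted_g2(proj, counts, floor) + 1e3 * sum((theta - proj)^2)
  }
  v0 <- objective(start)
  res <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  theta <- c(res$par, p_g = pg)
  theta <- pmin(pmax(theta, b$lower[names(theta)]), b$upper[names(theta)])
  est <- c(mu_g = theta[["mu_g"]], c1 = theta[["c1"]],
           c2 = theta[["c1"]] + theta[["dc2"]],
           c3 = theta[["c1"]] + theta[["dc2"]] + theta[["dc3"]],
           p_g = pg)
  structure(
    list(estimates = est, g_squared = .weighted_g2(theta, counts, floor),
         converged = res$convergence == 0L || v0 - res$value < 1e-8,
         boundary = c(mu_g_at_cap = est[["mu_g"]] >= mu_cap - 1e-6,
                      p_g_at_bound = FALSE),
         iterations = res$counts[["function"]], fixed_pg = pg,
         floor = floor, mu_cap = mu_cap,
         df = lineup_df(collapsed = TRUE), counts = counts),
    class = "lineup_fit"
  )
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat("Base-rate sensitivity profile\n")
  cat(sprintf("  grid: %d points in [%.2f, %.2f]\n",
              nrow(x$profile), min(x$profile$p_g), max(x$profile$p_g)))
  cat(sprintf("  best p_g = %.3f (G^2 = %.4f); reference p_g = %.3f (G^2 = %.4f)\n",
              x$best_pg, x$g2_min, x$reference_pg, x$g2_reference))
  cat(sprintf("  relative likelihood lr = %.3f\n", x$lr))
  invisible(x)
}

#' Parametric bootstrap of the base-rate estimate
#'
#' Gauges the sampling variability of the estimated base rate by repeatedly
#' simulating data from the fitted model — with the base rate held at a
#' stated value — and refitting the model with the base rate free. The
#' spread of the refit estimates around the generating value indicates how
#' much trust to place in a single estimate at that sample size.
#'
#' @param fit A `"lineup_fit"` object supplying the generating parameters.
#' @param fixed_pg Base rate used to generate the bootstrap data sets.
#' @param n_reps Number of simulate-and-refit cycles.
#' @param n Trials per simulated data set (default 1000).
#' @param k Lineup size for simulation (defaults to the fitted size).
#' @param seed Integer seed; the full study is reproducible given the seed.
#' @return Data frame with one row per replicate: `rep`, `p_g` (refit
#'   estimate), `g_squared`, `converged`, `mu_g_at_cap`.
#' @export
parametric_bootstrap <- function(fit, fixed_pg, n_reps, n = 1000, k = NULL,
                                 seed = 1) {
  stopifnot(inherits(fit, "lineup_fit"), n_reps >= 1, n >= 1,
            fixed_pg > 0, fixed_pg < 1)
  if (is.null(k)) k <- fit$counts$k[1]
  params <- fitted_params(fit, k = k)
  set.seed(seed)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    trials <- simulate_trials(sim_config(params, p_g = fixed_pg, n = n))
    refit <- tryCatch(
      fit_collapsed(collapse_table(trials), floor = fit$floor,
                    mu_cap = fit$mu_cap, n_restarts = 0),
      error = function(e) NULL)
    out[[r]] <- if (is.null(refit)) {
      data.frame(rep = r, p_g = NA_real_, g_squared = NA_real_,
                 converged = FALSE, mu_g_at_cap = NA)
    } else {
      data.frame(rep = r, p_g = refit$estimates[["p_g"]],
                 g_squared = refit$g_squared, converged = refit$converged,
                 mu_g_at_cap = refit$boundary[["mu_g_at_cap"]])
    }
  }
  do.call(rbind, out)
}
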