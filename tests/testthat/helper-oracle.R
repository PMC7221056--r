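# Independent Monte-Carlo oracle for the max-rule response probabilities.
# Deliberately naive: every lineup member's strength is drawn explicitly and
# the max rule is applied per trial, sharing no code with the package's
# quadrature or with simulate_trials() (which uses an inverse-CDF shortcut
# for the best filler).

mc_type_probs <- function(params, n_draws, guilty) {
  k <- params$k
  if (guilty) {
    suspect <- rnorm(n_draws, params$mu_g, params$sigma_g)
  } else {
    suspect <- rnorm(n_draws)
  }
  fillers <- matrix(rnorm(n_draws * (k - 1)), nrow = n_draws)
  best_filler <- do.call(pmax, as.data.frame(fillers))
  strongest <- pmax(suspect, best_filler)
  who <- ifelse(strongest < params$c1, "reject",
                ifelse(suspect > best_filler, "suspect", "filler"))
  bin <- c("low", "medium", "high")[findInterval(strongest, c(params$c2, params$c3)) + 1L]
  cat7 <- ifelse(who == "reject", "reject", paste(who, bin, sep = "_"))
  as.numeric(table(factor(cat7, levels = lineupSDT:::RESPONSE_CATEGORIES))) / n_draws
}

mc_collapsed_probs <- function(params, p_g, n_draws) {
  n_g <- round(n_draws * p_g)
  counts <- n_g * mc_type_probs(params, max(n_g, 1L), guilty = TRUE) +
    (n_draws - n_g) * mc_type_probs(params, max(n_draws - n_g, 1L), guilty = FALSE)
  counts / n_draws
}

# Random parameter set from the recovery-study uniform ranges.
random_study_params <- function(k = 6) {
  mu_g <- runif(1, 1.5, 3.5)
  c1 <- runif(1, 0.5, 1.5)
  c2 <- c1 + runif(1, 0.2, 0.4)
  c3 <- c2 + runif(1, 0.2, 0.7)
  list(params = lineup_params(mu_g, c1, c2, c3, k = k),
       p_g = runif(1, 0.2, 0.8))
}

expect_within_3se <- function(mc, exact, n_draws) {
  se <- sqrt(pmax(exact * (1 - exact), 1e-12) / n_draws)
  expect_true(all(abs(mc - exact) <= 3 * se + 1e-9),
              label = paste0("max |mc - exact| = ",
                             format(max(abs(mc - exact)), digits = 3),
                             " vs 3se bound ", format(max(3 * se), digits = 3)))
}
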