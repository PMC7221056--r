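#' Simulation configuration
#'
#' @param params A [lineup_params()] object (use `sigma_g != 1` to generate
#'   from an unequal-variance model).
#' @param p_g Base rate of guilty-suspect lineups in the simulated data set.
#' @param n Number of identification attempts (trials).
#' @param seed Optional integer seed applied by [simulate_trials()].
#' @param binomial_split If `TRUE`, the number of guilty lineups is drawn
#'   from Binomial(`n`, `p_g`); the default is the deterministic split
#'   `round(n * p_g)`, treating the base rate as a descriptive property of
#'   the data set.
#' @param rating_scale Optional integer `>= 2`: also emit a raw confidence
#'   rating rank on a `rating_scale`-point scale, drawn uniformly among the
#'   ranks whose normalized value falls in the trial's confidence bin.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(params, p_g, n, seed = NULL, binomial_split = FALSE,
                       rating_scale = NULL) {
  params <- as_lineup_params(params)
  stopifnot(p_g >= 0, p_g <= 1, n >= 1, n == round(n))
  if (!is.null(rating_scale)) stopifnot(rating_scale >= 2, rating_scale == round(rating_scale))
  structure(list(params = params, p_g = p_g, n = as.integer(n), seed = seed,
                 binomial_split = isTRUE(binomial_split),
                 rating_scale = rating_scale),
            class = "sim_config")
}

## Max of m iid N(0,1) via the inverse CDF of the maximum: if U ~ U(0,1)
## then qnorm(U^(1/m)) has CDF pnorm(x)^m. Exact and O(n) in the number of
## trials rather than O(n * m).
.rmax_std_normal <- function(n, m) {
  if (m == 0L) return(rep(-Inf, n))
  stats::qnorm(stats::runif(n)^(1 / m))
}

## Core max-rule generator for n lineups of one type.
## Returns response / confidence / max strength vectors.
.simulate_type <- function(n, params, guilty) {
  k <- params$k
  if (guilty) {
    suspect <- stats::rnorm(n, params$mu_g, params$sigma_g)
  } else {
    suspect <- stats::rnorm(n)            # innocent suspect is a lure
  }
  best_filler <- .rmax_std_normal(n, k - 1L)
  strongest <- pmax(suspect, best_filler)
  response <- rep("reject", n)
  idx <- strongest >= params$c1
  response[idx & suspect > best_filler] <- "suspect"
  response[idx & suspect <= best_filler] <- "filler"
  confidence <- rep(NA_character_, n)
  bin <- findInterval(strongest[idx], c(params$c2, params$c3)) + 1L
  confidence[idx] <- CONFIDENCE_LEVELS[bin]
  list(response = response, confidence = confidence)
}

## Draw a raw rating rank uniformly among ranks whose normalized confidence
## lies in the given bin (used to exercise normalization/binning round trips).
.rating_for_bin <- function(bin, scale_len) {
  ranks <- seq_len(scale_len)
  norm <- (ranks - 1) / (scale_len - 1)
  by_bin <- split(ranks, .confidence_bin(norm))
  vapply(bin, function(b) {
    pool <- by_bin[[b]]
    if (is.null(pool)) NA_integer_ else pool[sample.int(length(pool), 1L)]
  }, integer(1))
}

#' Simulate trial-level lineup identification data
#'
#' Generates per-trial records from the max-rule SDT process. A data set of
#' `n` identification attempts holds exactly `round(n * p_g)` guilty-suspect
#' (target-present) lineups and the remainder innocent-suspect
#' (target-absent) lineups. On a guilty lineup the suspect's strength is
#' drawn from the target distribution and the `k - 1` fillers' from the lure
#' distribution; on an innocent lineup the suspect's strength is also drawn
#' from the lure distribution. The strongest signal is compared to the
#' criteria: below `c1` the lineup is rejected, otherwise the strongest
#' member is identified with low/medium/high confidence.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `"trial_table"` with columns `trial`, `k`,
#'   `lineup_type` (`"guilty"`/`"innocent"`), `response`
#'   (`"suspect"`/`"filler"`/`"reject"`), `confidence` (`"low"`, `"medium"`,
#'   `"high"`, or `NA` for rejections), and, when `rating_scale` is set,
#'   `rating` and `rating_scale`.
#' @examples
#' cfg <- sim_config(lineup_params(2, 1, 1.5, 2, k = 6), p_g = 0.35,
#'                   n = 500, seed = 7)
#' head(simulate_trials(cfg))
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  n_g <- if (config$binomial_split) {
    stats::rbinom(1L, n, config$p_g)
  } else {
    round(n * config$p_g)
  }
  n_i <- n - n_g
  g <- .simulate_type(n_g, config$params, guilty = TRUE)
  i <- .simulate_type(n_i, config$params, guilty = FALSE)
  tab <- data.frame(
    trial = seq_len(n),
    k = config$params$k,
    lineup_type = rep(c("guilty", "innocent"), c(n_g, n_i)),
    response = c(g$response, i$response),
    confidence = c(g$confidence, i$confidence),
    stringsAsFactors = FALSE
  )
  if (!is.null(config$rating_scale)) {
    tab$rating <- NA_integer_
    idx <- tab$response != "reject"
    tab$rating[idx] <- .rating_for_bin(tab$confidence[idx], config$rating_scale)
    tab$rating_scale <- ifelse(idx, as.integer(config$rating_scale), NA_integer_)
  }
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Draw a random parameter set for recovery simulations
#'
#' Samples each generating parameter independently and uniformly from the
#' ranges used in the parameter-recovery studies:
#' `mu_g` in (1.5, 3.5), `c1` in (0.5, 1.5), criterion gaps
#' `c2 - c1` in (0.2, 0.4) and `c3 - c2` in (0.2, 0.7), and base rate
#' `p_g` in (0.2, 0.8).
#'
#' @param seed Optional integer seed.
#' @param n Trials for the returned configuration (default 1000).
#' @param k Lineup size (default 6).
#' @param sigma_g Target-distribution SD for generation (default 1).
#' @return A [sim_config()] with the sampled [lineup_params()] and `p_g`.
#' @export
sample_random_params <- function(seed = NULL, n = 1000, k = 6, sigma_g = 1) {
  if (!is.null(seed)) set.seed(seed)
  mu_g <- stats::runif(1, 1.5, 3.5)
  c1 <- stats::runif(1, 0.5, 1.5)
  dc2 <- stats::runif(1, 0.2, 0.4)
  dc3 <- stats::runif(1, 0.2, 0.7)
  p_g <- stats::runif(1, 0.2, 0.8)
  sim_config(lineup_params(mu_g, c1, c1 + dc2, c1 + dc2 + dc3, k = k,
                           sigma_g = sigma_g),
             p_g = p_g, n = n)
}

#' Resample a labeled trial table to a target base rate
#'
#' Builds a bootstrap data set with a controlled base rate of guilty
#' suspects: `round(n * base_rate)` trials drawn with replacement from the
#' guilty-lineup records and the remainder from the innocent-lineup records.
#'
#' @param labeled A `"trial_table"` containing both lineup types.
#' @param base_rate Target base rate in \[0, 1\].
#' @param n Size of the resampled data set (default 1000).
#' @param seed Optional integer seed.
#' @return A `"trial_table"` of `n` resampled records (trial ids renumbered).
#' @export
bootstrap_mix <- function(labeled, base_rate, n = 1000, seed = NULL) {
  stopifnot(inherits(labeled, "trial_table"), n >= 1,
            base_rate >= 0, base_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_g <- round(n * base_rate)
  n_i <- n - n_g
  g_pool <- which(labeled$lineup_type == "guilty")
  i_pool <- which(labeled$lineup_type == "innocent")
  if (n_g > 0 && length(g_pool) == 0) stop("no guilty-lineup records to resample from")
  if (n_i > 0 && length(i_pool) == 0) stop("no innocent-lineup records to resample from")
  rows <- c(if (n_g > 0) g_pool[sample.int(length(g_pool), n_g, replace = TRUE)],
            if (n_i > 0) i_pool[sample.int(length(i_pool), n_i, replace = TRUE)])
  out <- labeled[rows, , drop = FALSE]
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

.confidence_bin <- function(x) {
  ## boundary values 0.65 and 0.85 both fall in the medium bin
  ifelse(x < 0.65, "low", ifelse(x <= 0.85, "medium", "high"))
}

#' Normalize a confidence rating rank and assign its bin
#'
#' Studies use confidence scales of different lengths; to pool them, a
#' rating's rank is mapped to \[0, 1\] as `(rank - 1) / (n_levels - 1)` and
#' assigned to the low bin below 0.65, the medium bin between 0.65 and 0.85
#' (both endpoints inclusive), and the high bin above 0.85.
#'
#' @param rating_rank Integer rank(s) of the rating, `1 <= rank <= n_levels`.
#' @param n_levels Number of levels of the scale (`>= 2`).
#' @return A data frame with columns `value` (normalized confidence) and
#'   `bin` (`"low"`, `"medium"`, `"high"`).
#' @examples
#' normalize_confidence(4, 7)  # 0.50, low
#' @export
normalize_confidence <- function(rating_rank, n_levels) {
  stopifnot(length(n_levels) == 1, n_levels >= 2, n_levels == round(n_levels))
  if (any(rating_rank < 1 | rating_rank > n_levels | rating_rank != round(rating_rank))) {
    stop("rating_rank must be an integer in 1..n_levels")
  }
  value <- (rating_rank - 1) / (n_levels - 1)
  data.frame(value = value, bin = .confidence_bin(value),
             stringsAsFactors = FALSE)
}

#' Collapse a trial table to 7-category counts
#'
#' Pools guilty- and innocent-lineup records (discarding the guilt label,
#' as in investigative data) into the seven collapsed response-category
#' counts, per lineup size.
#'
#' @param labeled A `"trial_table"`.
#' @return A [collapsed_counts()] object, one row per lineup size; row
#'   totals equal the number of trials at each size.
#' @export
collapse_table <- function(labeled) {
  stopifnot(inherits(labeled, "trial_table"))
  ks <- sort(unique(labeled$k))
  counts <- t(vapply(ks, function(kk) {
    sub <- labeled[labeled$k == kk, ]
    cat7 <- ifelse(sub$response == "reject", "reject",
                   paste(sub$response, sub$confidence, sep = "_"))
    tab <- table(factor(cat7, levels = RESPONSE_CATEGORIES))
    as.integer(tab)
  }, integer(7)))
  collapsed_counts(ks, counts)
}
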