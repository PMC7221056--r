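#' Confidence-accuracy calibration from labeled trials
#'
#' Computes the two calibration curve families from a trial table in which
#' the guilt of the suspect is known on every trial:
#' \itemize{
#'   \item accuracy: the proportion of suspect identifications at each
#'     confidence level made to guilty suspects, plus the proportion of
#'     rejected lineups whose suspect was innocent (correct rejections);
#'   \item suspect share: the probability that a response at a given
#'     confidence level was a suspect identification (rather than a filler
#'     identification).
#' }
#' Cells with a zero denominator are returned as `NA` with `n = 0`, never
#' as zero accuracy.
#'
#' @param labeled A `"trial_table"` with known lineup types.
#' @return A data frame of class `"calibration_curve"` with columns `level`
#'   (`"low"`, `"medium"`, `"high"`, `"reject"`), `accuracy`, `n_accuracy`
#'   (denominator), `suspect_share`, `n_share`, and a `source` attribute
#'   `"data"`.
#' @export
calibration_from_trials <- function(labeled) {
  stopifnot(inherits(labeled, "trial_table"))
  if (any(labeled$lineup_type == "unknown")) {
    stop("calibration requires known lineup types on every trial")
  }
  rows <- lapply(CONFIDENCE_LEVELS, function(lvl) {
    susp <- labeled$response == "suspect" & labeled$confidence %in% lvl
    ids <- labeled$response != "reject" & labeled$confidence %in% lvl
    data.frame(
      level = lvl,
      accuracy = if (sum(susp)) mean(labeled$lineup_type[susp] == "guilty") else NA_real_,
      n_accuracy = sum(susp),
      suspect_share = if (sum(ids)) sum(susp) / sum(ids) else NA_real_,
      n_share = sum(ids))
  })
  rej <- labeled$response == "reject"
  rows[[4]] <- data.frame(
    level = "reject",
    accuracy = if (sum(rej)) mean(labeled$lineup_type[rej] == "innocent") else NA_real_,
    n_accuracy = sum(rej),
    suspect_share = NA_real_, n_share = NA_integer_)
  out <- do.call(rbind, rows)
  attr(out, "source") <- "data"
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Model-implied calibration curves
#'
#' The model analogue of [calibration_from_trials()]: the accuracy of a
#' suspect identification at confidence bin `b` is the posterior probability
#' of guilt given that response,
#' \deqn{\frac{p_g\,P(s_b \mid g)}{p_g\,P(s_b \mid g) + (1-p_g)\,P(s_b \mid i)},}
#' the rejection accuracy is the posterior probability of innocence given a
#' rejection, and the suspect share per bin comes from the collapsed
#' probabilities.
#'
#' @param params A [lineup_params()] object (or a `"lineup_fit"`, from which
#'   the fitted parameters and base rate are taken).
#' @param p_g Base rate; required when `params` is a `lineup_params`.
#' @return A `"calibration_curve"` data frame with `source` attribute
#'   `"model"`.
#' @export
calibration_from_model <- function(params, p_g = NULL) {
  if (inherits(params, "lineup_fit")) {
    if (is.null(p_g)) p_g <- params$estimates[["p_g"]]
    params <- fitted_params(params)
  }
  params <- as_lineup_params(params)
  if (is.null(p_g)) stop("p_g is required")
  stopifnot(p_g >= 0, p_g <= 1)
  g <- unclass(category_probs_guilty(params))
  i <- unclass(category_probs_innocent(params))
  susp <- paste0("suspect_", CONFIDENCE_LEVELS)
  fill <- paste0("filler_", CONFIDENCE_LEVELS)
  num <- p_g * g[susp]
  den <- p_g * g[susp] + (1 - p_g) * i[susp]
  share_den <- p_g * (g[susp] + g[fill]) + (1 - p_g) * (i[susp] + i[fill])
  share_num <- p_g * g[susp] + (1 - p_g) * i[susp]
  rej_den <- p_g * g[["reject"]] + (1 - p_g) * i[["reject"]]
  out <- data.frame(
    level = c(CONFIDENCE_LEVELS, "reject"),
    accuracy = c(ifelse(den > 0, num / den, NA_real_),
                 if (rej_den > 0) (1 - p_g) * i[["reject"]] / rej_den else NA_real_),
    n_accuracy = NA_integer_,
    suspect_share = c(ifelse(share_den > 0, share_num / share_den, NA_real_),
                      NA_real_),
    n_share = NA_integer_)
  rownames(out) <- NULL
  attr(out, "source") <- "model"
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' @export
print.calibration_curve <- function(x, digits = 3, ...) {
  cat(sprintf("Calibration curve (%s)\n", attr(x, "source")))
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

## Model PPG per confidence bin (suspect identifications), used by the
## simulation studies. sigma_g of `params` is honoured, so "actual" PPG in
## misspecification studies reflects the unequal-variance generator.
.ppg_by_confidence <- function(params, p_g) {
  g <- unclass(category_probs_guilty(params))
  i <- unclass(category_probs_innocent(params))
  susp <- paste0("suspect_", CONFIDENCE_LEVELS)
  num <- p_g * g[susp]
  den <- num + (1 - p_g) * i[susp]
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- CONFIDENCE_LEVELS
  out
}
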