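#' Posterior probability of guilt (PPG)
#'
#' Bayes' rule applied to an identification: the probability the identified
#' suspect is guilty, given the identification rates for guilty and innocent
#' suspects and the prior probability (base rate) that the lineup contains
#' the culprit:
#' \deqn{PPG = \frac{h\,p_g}{h\,p_g + f\,(1 - p_g)}}
#' with `h = p_id_guilty`, `f = p_id_innocent`.
#'
#' @param p_g Base rate of guilty suspects, in \[0, 1\].
#' @param p_id_guilty Probability the suspect is identified given guilty.
#' @param p_id_innocent Probability the suspect is identified given innocent.
#' @return A list of class `"ppg_result"` with elements `ppg`,
#'   `posterior_odds` (`ppg / (1 - ppg)`, `Inf` when `ppg == 1`) and
#'   `diagnosticity` (`NA` when `p_id_innocent == 0`).
#' @examples
#' ppg(0.35, 0.46, 0.03)  # roughly 0.9
#' ppg(0.35, 0.31, 0.07)  # about 0.7
#' @export
ppg <- function(p_g, p_id_guilty, p_id_innocent) {
  vals <- c(p_g = p_g, p_id_guilty = p_id_guilty, p_id_innocent = p_id_innocent)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("p_g and identification rates must lie in [0, 1]")
  }
  denom <- p_id_guilty * p_g + p_id_innocent * (1 - p_g)
  if (denom <= 0) {
    stop("PPG undefined: the probability of an identification is zero")
  }
  val <- p_id_guilty * p_g / denom
  structure(
    list(ppg = val,
         posterior_odds = if (val < 1) val / (1 - val) else Inf,
         diagnosticity = if (p_id_innocent > 0) p_id_guilty / p_id_innocent else NA_real_),
    class = "ppg_result"
  )
}

#' @export
print.ppg_result <- function(x, ...) {
  cat(sprintf("PPG = %.4f  (posterior odds %.4g", x$ppg, x$posterior_odds))
  if (is.finite(x$diagnosticity)) cat(sprintf(", diagnosticity %.4g", x$diagnosticity))
  cat(")\n")
  invisible(x)
}

#' Diagnosticity ratio
#'
#' Likelihood ratio of a suspect identification: the probability the culprit
#' is identified divided by the probability an innocent suspect is
#' identified.
#'
#' @inheritParams ppg
#' @return The ratio `p_id_guilty / p_id_innocent`.
#' @examples
#' diagnosticity(0.46, 0.03)  # 15.3
#' @export
diagnosticity <- function(p_id_guilty, p_id_innocent) {
  if (!is.finite(p_id_guilty) || !is.finite(p_id_innocent) ||
      p_id_guilty < 0 || p_id_innocent < 0) {
    stop("identification rates must be non-negative")
  }
  if (p_id_innocent == 0) stop("diagnosticity undefined: innocent identification rate is zero")
  p_id_guilty / p_id_innocent
}

#' Posterior odds of guilt
#'
#' Odds form of Bayes' rule: posterior odds equal the diagnosticity ratio
#' times the prior odds of guilt.
#'
#' @param diag Diagnosticity ratio (non-negative).
#' @param prior_odds Prior odds of guilt, `p_g / (1 - p_g)` (non-negative).
#' @return `diag * prior_odds`.
#' @examples
#' posterior_odds(15.3, 0.01)  # about 0.15
#' @export
posterior_odds <- function(diag, prior_odds) {
  if (!is.finite(diag) || !is.finite(prior_odds) || diag < 0 || prior_odds < 0) {
    stop("diagnosticity and prior odds must be non-negative")
  }
  diag * prior_odds
}

#' Minimum base rate needed to reach a PPG threshold
#'
#' Inverts the PPG equation for the base rate: the smallest prior
#' P(guilty) at which the posterior probability of guilt reaches
#' `ppg_threshold`, given the identification rates. Closed form:
#' \deqn{p_g = \frac{t f}{h (1 - t) + t f}}
#' with `t` the threshold, `h = p_id_guilty`, `f = p_id_innocent`.
#'
#' @param ppg_threshold Required PPG, in (0, 1); e.g. 0.95 for a
#'   beyond-reasonable-doubt standard.
#' @inheritParams ppg
#' @return The minimum base rate in \[0, 1\].
#' @examples
#' min_base_rate_for_ppg(0.95, 0.46, 0.03)  # 0.55: base rate must be >= 55%
#' min_base_rate_for_ppg(0.95, 0.31, 0.07)  # 0.81
#' @export
min_base_rate_for_ppg <- function(ppg_threshold, p_id_guilty, p_id_innocent) {
  if (!is.finite(ppg_threshold) || ppg_threshold <= 0 || ppg_threshold >= 1) {
    stop("ppg_threshold must lie strictly inside (0, 1)")
  }
  if (p_id_guilty <= 0 || p_id_guilty > 1 || p_id_innocent <= 0 || p_id_innocent > 1) {
    stop("identification rates must lie in (0, 1]")
  }
  t <- ppg_threshold
  t * p_id_innocent / (p_id_guilty * (1 - t) + t * p_id_innocent)
}
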