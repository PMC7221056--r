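#' Lineup SDT model parameters
#'
#' Bundle the parameters of the max-rule signal detection model for a
#' simultaneous lineup: the guilty-suspect (target) memory-strength
#' distribution N(`mu_g`, `sigma_g`), the filler/lure reference distribution
#' fixed at N(0, 1), three confidence criteria, and the lineup size.
#'
#' A witness is assumed to compare the strongest memory signal among the `k`
#' lineup members to the criteria: below `c1` the lineup is rejected; signals
#' in `[c1, c2)`, `[c2, c3)`, and `[c3, Inf)` produce identifications with
#' low, medium, and high confidence respectively.
#'
#' @param mu_g Mean of the guilty-suspect strength distribution, in
#'   standardized (lure SD) units.
#' @param c1,c2,c3 Confidence criteria, strictly increasing.
#' @param k Lineup size (number of photos), integer `>= 2`.
#' @param sigma_g SD of the guilty-suspect distribution. Default 1
#'   (equal-variance model). Values other than 1 are used only for
#'   data generation in misspecification studies; fitting always
#'   constrains `sigma_g = 1`.
#'
#' @return An object of class `"lineup_params"`: a list with elements
#'   `mu_g`, `sigma_g`, `mu_f` (0), `sigma_f` (1), `c1`, `c2`, `c3`, `k`.
#' @examples
#' p <- lineup_params(mu_g = 2, c1 = 1, c2 = 1.5, c3 = 2, k = 6)
#' category_probs_guilty(p)
#' @export
lineup_params <- function(mu_g, c1, c2, c3, k = 6, sigma_g = 1) {
  vals <- c(mu_g = mu_g, sigma_g = sigma_g, c1 = c1, c2 = c2, c3 = c3, k = k)
  if (!all(is.finite(vals))) {
    stop("all lineup parameters must be finite; got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (sigma_g <= 0) stop("sigma_g must be > 0")
  if (!(c1 < c2 && c2 < c3)) {
    stop("confidence criteria must be strictly ordered: c1 < c2 < c3 (got ",
         c1, ", ", c2, ", ", c3, ")")
  }
  if (k != round(k) || k < 2) stop("lineup size k must be an integer >= 2")
  structure(
    list(mu_g = as.numeric(mu_g), sigma_g = as.numeric(sigma_g),
         mu_f = 0, sigma_f = 1,
         c1 = as.numeric(c1), c2 = as.numeric(c2), c3 = as.numeric(c3),
         k = as.integer(k)),
    class = "lineup_params"
  )
}

#' @export
print.lineup_params <- function(x, ...) {
  cat("Lineup SDT parameters (max rule)\n")
  cat(sprintf("  target: N(%.3f, %.3f)   lures: N(0, 1)   k = %d\n",
              x$mu_g, x$sigma_g, x$k))
  cat(sprintf("  criteria: c1 = %.3f  c2 = %.3f  c3 = %.3f\n",
              x$c1, x$c2, x$c3))
  invisible(x)
}

as_lineup_params <- function(x) {
  if (inherits(x, "lineup_params")) return(x)
  stop("expected a 'lineup_params' object; see lineup_params()")
}

#' Degrees of freedom of lineup identification data
#'
#' Bookkeeping for the identification-frequency data the model is fit to.
#' With `m` confidence levels there are `2 * m + 1` response categories per
#' lineup type (suspect or filler identification at each confidence level,
#' plus rejection), and each lineup type loses one degree of freedom to the
#' fixed total. Data in which the guilt of the suspect is known carry both
#' lineup types; collapsed data (guilt unknown) pool them into a single set
#' of frequencies.
#'
#' @param n_levels Number of confidence levels (default 3).
#' @param collapsed If `TRUE` (default), degrees of freedom of the collapsed
#'   7-category data; if `FALSE`, of the uncollapsed two-lineup-type data.
#' @return Integer degrees of freedom: 6 collapsed, 12 uncollapsed for 3
#'   confidence levels.
#' @export
lineup_df <- function(n_levels = 3, collapsed = TRUE) {
  stopifnot(n_levels >= 1)
  per_type <- 2L * as.integer(n_levels)  # (2m + 1 categories) - 1
  if (collapsed) per_type else 2L * per_type
}
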