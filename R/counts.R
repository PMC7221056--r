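#' Collapsed identification counts
#'
#' Observed frequencies of the seven collapsed response categories, one row
#' per lineup size. This is the data format the model is fit to: guilt
#' status is unknown, so guilty- and innocent-suspect trials are pooled.
#'
#' @param k Integer vector of lineup sizes, one per row.
#' @param counts Numeric matrix (or a single vector for one lineup size)
#'   with 7 columns in canonical category order: suspect identifications at
#'   low/medium/high confidence, filler identifications at low/medium/high
#'   confidence, rejections.
#' @return A data frame of class `"collapsed_counts"` with columns `k`, the
#'   seven category counts, and `n` (row total).
#' @examples
#' collapsed_counts(6, c(30, 25, 45, 60, 30, 10, 300))
#' @export
collapsed_counts <- function(k, counts) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (ncol(counts) != 7L) stop("counts must have 7 columns (one per response category)")
  if (length(k) != nrow(counts)) stop("one lineup size per row of counts is required")
  if (any(k != round(k) | k < 2)) stop("lineup sizes must be integers >= 2")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(duplicated(k))) stop("duplicated lineup size; pool counts per size first")
  n <- rowSums(counts)
  if (any(n == 0)) stop("every lineup size must have at least one observed trial")
  out <- data.frame(k = as.integer(k), counts, n = as.integer(n))
  names(out) <- c("k", RESPONSE_CATEGORIES, "n")
  class(out) <- c("collapsed_counts", "data.frame")
  out
}

count_matrix <- function(counts) {
  as.matrix(counts[, RESPONSE_CATEGORIES, drop = FALSE])
}

#' @export
print.collapsed_counts <- function(x, ...) {
  cat("Collapsed lineup identification counts\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' G-squared fit statistic for collapsed counts
#'
#' Likelihood-ratio statistic between observed category counts and model
#' predictions: \eqn{G^2 = 2 \sum O \ln(O / (N \tilde p))}, where the
#' predicted probability of each cell is floored at `floor` (default 0.001;
#' model predictions are not allowed below the floor, and floored values are
#' not renormalized) and cells with zero observed count are excluded from
#' the sum.
#'
#' @param observed Numeric vector of 7 observed counts in canonical category
#'   order (or a one-row [collapsed_counts()] object).
#' @param predicted A [response_distribution()] of collapsed model
#'   probabilities for the same lineup size.
#' @param floor Lower bound applied to predicted cell probabilities.
#' @return Non-negative statistic (0 when observed proportions match the
#'   floored predictions exactly).
#' @export
g_squared <- function(observed, predicted, floor = 0.001) {
  if (inherits(observed, "collapsed_counts")) {
    if (nrow(observed) != 1L) stop("g_squared takes counts for a single lineup size")
    observed <- count_matrix(observed)[1, ]
  }
  observed <- as.numeric(observed)
  if (length(observed) != 7L) stop("observed must hold 7 category counts")
  if (all(observed == 0)) stop("all-zero counts: nothing to fit")
  p <- pmax(as.numeric(predicted), floor)
  n <- sum(observed)
  keep <- observed > 0
  2 * sum(observed[keep] * log(observed[keep] / (n * p[keep])))
}
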