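## Comma-delimited, header required, UTF-8. One dialect, no autodetection.

TRIAL_COLUMNS <- c("trial", "k", "lineup_type", "response", "confidence")
LINEUP_TYPES <- c("guilty", "innocent", "unknown")

#' Write a trial table to CSV
#'
#' @param table A `"trial_table"`.
#' @param path Output file path. Rejection rows carry an empty confidence
#'   field.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  out <- as.data.frame(table)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial table from CSV
#'
#' Expects the header written by [write_trial_table()]: `trial`, `k`,
#' `lineup_type`, `response`, `confidence`, optionally `rating` and
#' `rating_scale`. Every malformed row is reported with its row number;
#' category labels are never silently coerced.
#'
#' @param path CSV file path.
#' @return A validated `"trial_table"`.
#' @export
read_trial_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$trial <- suppressWarnings(as.integer(raw$trial))
  raw$k <- suppressWarnings(as.integer(raw$k))
  raw$confidence[raw$confidence == ""] <- NA_character_

  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, paste0(what, " (row ",
                                      paste(rows, collapse = ", "), ")"))
    }
  }
  rn <- seq_len(nrow(raw))
  note(rn[is.na(raw$trial)], "non-integer trial id")
  note(rn[is.na(raw$k) | raw$k < 2], "lineup size k must be an integer >= 2")
  note(rn[!raw$lineup_type %in% LINEUP_TYPES],
       paste0("lineup_type must be one of ", paste(LINEUP_TYPES, collapse = "/")))
  note(rn[!raw$response %in% c("suspect", "filler", "reject")],
       "response must be suspect/filler/reject")
  note(rn[raw$response == "reject" & !is.na(raw$confidence)],
       "reject rows must not carry a confidence bin")
  note(rn[raw$response %in% c("suspect", "filler") &
            !raw$confidence %in% CONFIDENCE_LEVELS],
       "identification rows need confidence low/medium/high")
  if ("rating" %in% names(raw)) {
    raw$rating <- suppressWarnings(as.integer(raw$rating))
    raw$rating_scale <- suppressWarnings(as.integer(raw$rating_scale))
    bad <- !is.na(raw$rating) &
      (is.na(raw$rating_scale) | raw$rating < 1 | raw$rating > raw$rating_scale)
    note(rn[bad], "rating outside 1..rating_scale")
  }
  if (length(problems)) {
    stop("invalid trial table '", path, "':\n  ",
         paste(problems, collapse = "\n  "))
  }
  class(raw) <- c("trial_table", "data.frame")
  raw
}

#' Write collapsed counts to CSV
#'
#' One row per lineup size with the seven category counts and the row total.
#'
#' @param counts A [collapsed_counts()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "collapsed_counts"))
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read collapsed counts from CSV
#'
#' @param path CSV written by [write_counts()] (columns `k`, the seven
#'   category counts, optionally `n`).
#' @return A validated [collapsed_counts()] object.
#' @export
read_counts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("k", RESPONSE_CATEGORIES), names(raw))
  if (length(missing_cols)) {
    stop("counts file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  collapsed_counts(raw$k, as.matrix(raw[, RESPONSE_CATEGORIES]))
}

#' Write a fit result as a one-row delimited table
#'
#' @param fit A `"lineup_fit"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "lineup_fit"))
  row <- data.frame(
    mu_g = fit$estimates[["mu_g"]], c1 = fit$estimates[["c1"]],
    c2 = fit$estimates[["c2"]], c3 = fit$estimates[["c3"]],
    p_g = fit$estimates[["p_g"]], g_squared = fit$g_squared,
    converged = fit$converged,
    mu_g_at_cap = fit$boundary[["mu_g_at_cap"]],
    p_g_at_bound = fit$boundary[["p_g_at_bound"]],
    df = fit$df)
  utils::write.csv(row, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sensitivity profile as two-column delimited text
#'
#' @param profile A `"sensitivity_profile"`.
#' @param path Output file path; columns `p_g`, `g_squared`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  utils::write.csv(profile$profile[, c("p_g", "g_squared")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run-metadata sidecar
#'
#' Plain-text `key = value` lines capturing everything needed to reproduce
#' a run: the subcommand or function, the seed, every configuration value,
#' and the package version.
#'
#' @param path Sidecar file path (conventionally `<output>.meta`).
#' @param ... Named values to record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, ...) {
  vals <- list(...)
  vals$package <- paste0("lineupSDT ",
                         as.character(utils::packageVersion("lineupSDT")))
  lines <- vapply(names(vals), function(nm) {
    paste0(nm, " = ", paste(format(vals[[nm]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
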