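#' Composite error score and correctness classification
#'
#' Each certificate's score weights its error types: two points per major
#' error (multiple causes per line, missing time interval, incorrect
#' sequence, ill-defined underlying cause) and one point per minor error
#' (blank lines, abbreviations, additional errors). Each error type counts
#' once regardless of how many lines exhibit it, and the additional-errors
#' type contributes at most one point regardless of how many subtypes fired,
#' so the score ranges 0 to 11. A certificate is correct iff it has no error
#' at all (score 0). Weights are configurable for sensitivity analysis; the
#' defaults are the published 2/1 weighting.
#'
#' @param profiles error-profile data.frame from [assess_certificates()]
#'   (the seven error-type flag columns are required).
#' @param major_weight points per major error (default 2).
#' @param minor_weight points per minor error (default 1).
#' @return data.frame with columns `n_major`, `n_minor`, `n_errors`, `score`,
#'   `correct`.
#' @export
score_profiles <- function(profiles, major_weight = 2L, minor_weight = 1L) {
  missing <- setdiff(ERROR_TYPES, names(profiles))
  if (length(missing) > 0L) {
    stop("profiles are missing flag column(s): ",
         paste(missing, collapse = ", "))
  }
  maj <- as.matrix(profiles[MAJOR_ERRORS])
  min_ <- as.matrix(profiles[MINOR_ERRORS])
  if (any(is.na(maj)) || any(is.na(min_))) stop("error flags must not be NA")
  n_major <- as.integer(rowSums(maj))
  n_minor <- as.integer(rowSums(min_))
  score <- major_weight * n_major + minor_weight * n_minor
  data.frame(n_major = n_major, n_minor = n_minor,
             n_errors = n_major + n_minor,
             score = score,
             correct = n_major + n_minor == 0L)
}

#' Band an error count as 0, 1, 2, 3 or 4+
#'
#' The banding used by the correctness distribution table; the top band is
#' open-ended ("four or more errors").
#'
#' @param n_errors integer vector of per-certificate error counts.
#' @return factor with levels `0`, `1`, `2`, `3`, `4+`.
#' @export
error_count_band <- function(n_errors) {
  stopifnot(all(n_errors >= 0))
  lab <- ifelse(n_errors >= 4L, "4+", as.character(n_errors))
  factor(lab, levels = c("0", "1", "2", "3", "4+"))
}
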