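# Group-level summary tables ----------------------------------------------

ARM_LEVELS <- CERT_ENUMS$arm
ARM_PCT_COLUMNS <- paste0("pct_", ARM_LEVELS)

check_arms <- function(arm) {
  bad <- setdiff(unique(arm), ARM_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown study-arm label(s): ", paste(bad, collapse = ", "))
  }
  present <- ARM_LEVELS[ARM_LEVELS %in% arm]
  if (length(present) < length(ARM_LEVELS)) {
    warning("not all three study arms present; ",
            "improvement columns are omitted")
  }
  present
}

#' Percentage-point improvement
#'
#' The arithmetic difference between a pre-intervention and a
#' post-intervention prevalence, in percentage points; positive values mean
#' the error became rarer. Computed on unrounded percentages; round only at
#' presentation.
#'
#' @param p_pre,p_post percentages in \[0, 100\] (vectorized).
#' @return `p_pre - p_post`, in percentage points.
#' @export
#' @examples
#' improvement(96.0, 30.0) # 66 points
improvement <- function(p_pre, p_post) {
  if (any(p_pre < 0 | p_pre > 100, na.rm = TRUE) ||
      any(p_post < 0 | p_post > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]")
  }
  p_pre - p_post
}

#' Distribution of error counts by study arm
#'
#' Tabulates certificates into error-count bands (0, 1, 2, 3, 4+) with
#' column percentages per arm; each arm's percentages sum to 100 up to
#' rounding. When all three arms are present, percentage-point improvement
#' columns are added for the correct (band 0) row: pre-intervention minus
#' each intervention arm, computed on unrounded percentages.
#'
#' @param assessment data.frame with columns `arm` and `n_errors` (e.g. from
#'   [read_assessment()] joined with [score_profiles()] output).
#' @return data.frame with one row per band, unrounded percentage columns
#'   per arm and (when applicable) improvement columns.
#' @export
correctness_table <- function(assessment) {
  stopifnot(all(c("arm", "n_errors") %in% names(assessment)))
  if (nrow(assessment) == 0L) stop("no certificates to tabulate")
  present <- check_arms(assessment$arm)
  band <- error_count_band(assessment$n_errors)
  counts <- table(band, factor(assessment$arm, levels = present))
  pct <- sweep(counts, 2L, colSums(counts), "/") * 100
  out <- data.frame(band = rownames(pct), stringsAsFactors = FALSE)
  for (a in present) out[[paste0("pct_", a)]] <- as.numeric(pct[, a])
  if (length(present) == length(ARM_LEVELS)) {
    # correctness rises with the interventions, so the improvement for the
    # correct row is intervention minus pre-intervention
    corr <- out$band == "0"
    out$improvement_online <- ifelse(
      corr, improvement(out$pct_online, out$pct_pre_intervention), NA_real_)
    out$improvement_online_training <- ifelse(
      corr, improvement(out$pct_online_training, out$pct_pre_intervention),
      NA_real_)
  }
  out
}

#' Per-arm prevalence of each error type
#'
#' One row per error type (major, minor, and the additional-error subtypes),
#' with the percentage of certificates flagged in each arm and, when all
#' three arms are present, percentage-point improvements (pre-intervention
#' minus each intervention arm) for the seven error types. Subtype rows are
#' reported under additional errors without improvement columns.
#'
#' @param assessment data.frame with column `arm` and the error flag columns
#'   (see [assess_certificates()]).
#' @return data.frame keyed by `error_type` with a `class` column
#'   (major / minor / subtype) and unrounded percentage columns.
#' @export
prevalence_table <- function(assessment) {
  stopifnot("arm" %in% names(assessment),
            all(c(ERROR_TYPES, ERROR_SUBTYPES) %in% names(assessment)))
  if (nrow(assessment) == 0L) stop("no certificates to tabulate")
  present <- check_arms(assessment$arm)
  types <- c(ERROR_TYPES, ERROR_SUBTYPES)
  cls <- c(rep("major", length(MAJOR_ERRORS)),
           rep("minor", length(MINOR_ERRORS)),
           rep("subtype", length(ERROR_SUBTYPES)))
  out <- data.frame(error_type = types, class = cls,
                    stringsAsFactors = FALSE)
  arm <- factor(assessment$arm, levels = present)
  for (a in present) {
    sel <- arm == a
    out[[paste0("pct_", a)]] <-
      vapply(types, function(tp) 100 * mean(assessment[[tp]][sel]), numeric(1))
  }
  if (length(present) == length(ARM_LEVELS)) {
    main <- out$class != "subtype"
    out$improvement_online <- ifelse(
      main, improvement(out$pct_pre_intervention, out$pct_online), NA_real_)
    out$improvement_online_training <- ifelse(
      main, improvement(out$pct_pre_intervention, out$pct_online_training),
      NA_real_)
  }
  out
}

# Age in years regardless of recording unit; a missing unit is read as years
# (the missing unit itself is an additional-error subtype, not a data gap).
age_in_years <- function(age_value, age_unit) {
  unit <- as.character(age_unit)
  unit[is.na(unit) | unit == ""] <- "years"
  age_value / c(days = 365.25, months = 12, years = 1)[unit]
}

AGE_BANDS <- c("0-4", "5-44", "45-64", "65-74", "75-84", ">=85")
MONTHS_BANDS <- c("<3", "3-6", ">6")

age_band <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 5, 45, 65, 75, 85, Inf),
      labels = AGE_BANDS, right = FALSE)
}

# <3 months, 3-6 months (both bounds inclusive), >6 months
months_band <- function(months) {
  out <- rep(NA_character_, length(months))
  out[!is.na(months) & months < 3] <- "<3"
  out[!is.na(months) & months >= 3 & months <= 6] <- "3-6"
  out[!is.na(months) & months > 6] <- ">6"
  factor(out, levels = MONTHS_BANDS)
}

#' Any-error percentage and mean score by attribute category
#'
#' Summarises certification quality per category of each deceased/certifier
#' attribute: age band, sex, GBD cause group, certifier seniority band,
#' speciality, facility level and months since training. Categories with no
#' certificates are omitted. Months-since-training rows cover only
#' certificates with a recorded training time (this excludes the
#' pre-intervention arm by construction).
#'
#' @param batch certificate batch data.frame.
#' @param scores score data.frame from [score_profiles()], row-aligned with
#'   `batch`.
#' @return data.frame with columns `attribute`, `category`, `n`,
#'   `any_error_pct`, `mean_score`.
#' @export
attribute_summary <- function(batch, scores) {
  if (nrow(batch) != nrow(scores)) {
    stop("batch and scores must have one row per certificate")
  }
  if (nrow(batch) == 0L) stop("no certificates to summarise")
  any_error <- !scores$correct
  score <- scores$score

  groups <- list(
    age_band = age_band(age_in_years(batch$age_value, batch$age_unit)),
    sex = factor(batch$sex, levels = CERT_ENUMS$sex),
    gbd_group = factor(batch$gbd_group, levels = CERT_ENUMS$gbd_group),
    seniority_years = factor(batch$seniority_years,
                             levels = CERT_ENUMS$seniority_years),
    speciality = factor(batch$speciality, levels = CERT_ENUMS$speciality),
    facility_level = factor(batch$facility_level,
                            levels = CERT_ENUMS$facility_level),
    months_since_training = months_band(batch$months_since_training)
  )
  rows <- lapply(names(groups), function(attr) {
    g <- groups[[attr]]
    keep <- !is.na(g)
    if (!any(keep)) return(NULL)
    n <- tapply(rep(1L, sum(keep)), g[keep], sum)
    pct <- tapply(any_error[keep], g[keep], function(x) 100 * mean(x))
    ms <- tapply(score[keep], g[keep], mean)
    nonzero <- !is.na(n) & n > 0
    data.frame(attribute = attr, category = names(n)[nonzero],
               n = as.integer(n[nonzero]),
               any_error_pct = as.numeric(pct[nonzero]),
               mean_score = as.numeric(ms[nonzero]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a summary table as aligned plain text
#'
#' Numeric columns are rounded to one decimal (the display precision of the
#' published tables); alignment is column-wise.
#'
#' @param table a data.frame from one of the tabulation functions.
#' @param digits decimal places for numeric columns.
#' @return character vector of lines.
#' @export
render_table_text <- function(table, digits = 1) {
  stopifnot(is.data.frame(table))
  fmt <- table
  for (cl in names(fmt)) {
    if (is.numeric(fmt[[cl]]) && !is.integer(fmt[[cl]])) {
      fmt[[cl]] <- ifelse(is.na(fmt[[cl]]), "",
                          formatC(round(fmt[[cl]], digits),
                                  format = "f", digits = digits))
    }
  }
  body <- vapply(names(fmt), function(cl) {
    format(c(cl, as.character(fmt[[cl]])), justify = "right")
  }, character(nrow(fmt) + 1L))
  body <- matrix(body, nrow = nrow(fmt) + 1L)
  apply(body, 1L, paste, collapse = "  ")
}
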