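# Certificate batch schema -----------------------------------------------
#
# A certificate batch is a plain data.frame, one row per certificate, with
# the flat CSV schema below. Part 1 holds up to four cause lines (line "a" at
# position 1 is the immediate cause; the lowest used line carries the
# underlying cause); each line's time interval is encoded "value;unit" in a
# single column so the schema stays flat.

CERT_COLUMNS <- c(
  "certificate_id",
  "cause1a", "interval1a", "cause1b", "interval1b",
  "cause1c", "interval1c", "cause1d", "interval1d",
  "part2",
  "age_value", "age_unit", "sex", "gbd_group", "arm",
  "seniority_years", "speciality", "facility_level",
  "months_since_training"
)

CAUSE_COLUMNS <- paste0("cause1", letters[1:4])
INTERVAL_COLUMNS <- paste0("interval1", letters[1:4])
INTERVAL_UNITS <- c("minutes", "hours", "days", "weeks", "months", "years")

CERT_ENUMS <- list(
  age_unit = c("days", "months", "years"),
  sex = c("male", "female"),
  gbd_group = c("communicable", "non_communicable", "external", "ill_defined"),
  arm = c("pre_intervention", "online", "online_training"),
  seniority_years = c("0-5", "6-10", "11-15", "16-20", "21-25", "26-30", ">30"),
  speciality = c("general_medicine", "internal_medicine",
                 "pediatrics_neonatology", "intensive_care", "pneumology",
                 "oncology", "emergency", "general_surgery", "other"),
  facility_level = c("I", "II", "III")
)
# enum fields where an empty value means "absent"
CERT_ENUM_OPTIONAL <- c("age_unit")

MAJOR_ERRORS <- c("multiple_causes_per_line", "missing_time_interval",
                  "incorrect_sequence", "ill_defined_ucod")
MINOR_ERRORS <- c("blank_lines", "abbreviations", "additional_errors")
ERROR_TYPES <- c(MAJOR_ERRORS, MINOR_ERRORS)
ERROR_SUBTYPES <- c("external_missing_details", "neoplasm_missing_details",
                    "age_no_units", "other_additional")

#' An empty certificate batch
#'
#' @return a zero-row data.frame with the full certificate schema.
#' @export
empty_certificate_batch <- function() {
  cols <- stats::setNames(rep(list(character(0)), length(CERT_COLUMNS)),
                          CERT_COLUMNS)
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  out$age_value <- numeric(0)
  out$months_since_training <- numeric(0)
  out
}

#' Read a batch of certificates from CSV
#'
#' Reads a certificate CSV (comma-separated, UTF-8, header row) into the
#' standard batch data.frame. An optional column/value mapping adapts foreign
#' schemas: `mapping$columns` renames source columns to the standard names and
#' `mapping$values` recodes raw cell values per column (e.g. `"M"` to
#' `"male"`). Enumerations are parsed case-insensitively; empty strings become
#' absent values where the schema allows.
#'
#' @param path path to a CSV file (an empty file yields an empty batch).
#' @param mapping optional list with elements `columns` (named character
#'   vector, `standard = source`) and `values` (named list of named character
#'   vectors, `column = c(source = standard)`).
#' @return a data.frame with the columns of [empty_certificate_batch()].
#' @export
read_certificates <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("certificate file not found: ", path)
  if (file.size(path) == 0L) return(empty_certificate_batch())
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!is.null(mapping$columns)) {
    for (std in names(mapping$columns)) {
      src <- mapping$columns[[std]]
      if (!src %in% names(raw)) {
        stop("mapped source column not found: ", src)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  missing <- setdiff(CERT_COLUMNS, names(raw))
  if (length(missing) > 0L) {
    stop("certificate CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  batch <- raw[CERT_COLUMNS]
  if (nrow(batch) == 0L) return(empty_certificate_batch())

  for (col in names(mapping$values %||% list())) {
    map <- mapping$values[[col]]
    hit <- batch[[col]] %in% names(map)
    batch[[col]][hit] <- unname(map[batch[[col]][hit]])
  }

  for (col in names(CERT_ENUMS)) {
    levels <- CERT_ENUMS[[col]]
    val <- trimws(batch[[col]])
    idx <- match(tolower(val), tolower(levels))
    blank <- val == ""
    bad <- is.na(idx) & !blank
    if (col %in% CERT_ENUM_OPTIONAL) {
      # blanks allowed
    } else if (any(blank)) {
      bad <- bad | blank
    }
    if (any(bad)) {
      stop(sprintf("row %d: cannot parse %s value '%s'",
                   which(bad)[1L], col, val[which(bad)[1L]]))
    }
    out <- ifelse(blank, "", levels[idx])
    batch[[col]] <- out
  }

  for (col in c("age_value", "months_since_training")) {
    val <- trimws(batch[[col]])
    num <- suppressWarnings(as.numeric(val))
    bad <- is.na(num) & val != ""
    if (any(bad)) {
      stop(sprintf("row %d: cannot parse %s value '%s'",
                   which(bad)[1L], col, val[which(bad)[1L]]))
    }
    batch[[col]] <- num
  }
  if (anyNA(batch$age_value)) {
    stop(sprintf("row %d: age_value is missing",
                 which(is.na(batch$age_value))[1L]))
  }
  rownames(batch) <- NULL
  batch
}

#' Write a batch of certificates to CSV
#'
#' @param batch a certificate batch data.frame.
#' @param path output path.
#' @export
write_certificates <- function(batch, path) {
  stopifnot(all(CERT_COLUMNS %in% names(batch)))
  out <- batch[CERT_COLUMNS]
  out$months_since_training[is.na(out$months_since_training)] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Parse "value;unit" interval encodings; returns data.frame(value, unit) with
# NA for absent/unparseable entries and an `ok` flag (TRUE for absent too).
parse_interval <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  pat <- paste0("^([0-9]+(\\.[0-9]+)?)\\s*;\\s*(",
                paste(INTERVAL_UNITS, collapse = "|"), ")$")
  m <- regmatches(x, regexec(pat, tolower(x)))
  value <- vapply(m, function(g) if (length(g)) as.numeric(g[2L]) else NA_real_,
                  numeric(1))
  unit <- vapply(m, function(g) if (length(g)) g[4L] else NA_character_,
                 character(1))
  data.frame(value = value, unit = unit,
             ok = x == "" | !is.na(value),
             present = x != "",
             stringsAsFactors = FALSE)
}

#' Structural validation of a certificate batch
#'
#' Reports structural problems (data defects) as findings; these are distinct
#' from the certification errors assessed by [assess_certificates()]. An
#' empty result means the batch is structurally valid.
#'
#' Checked: interval encodings must parse as "value;unit" (a value without a
#' unit, or vice versa, is a finding); an interval on an empty cause line; at
#' least one Part 1 line must carry a cause; a leading blank line (empty line
#' "a" before used lines) is flagged here, not by the blank-lines error rule,
#' which only covers blanks strictly within the chain; pre-intervention
#' certificates must not carry months-since-training; negative ages.
#'
#' @param batch a certificate batch data.frame.
#' @return data.frame with columns `row`, `certificate_id`, `field`,
#'   `message`; zero rows when valid.
#' @export
validate_certificates <- function(batch) {
  findings <- list()
  add <- function(rows, field, message) {
    if (any(rows)) {
      findings[[length(findings) + 1L]] <<- data.frame(
        row = which(rows),
        certificate_id = batch$certificate_id[rows],
        field = field, message = message, stringsAsFactors = FALSE)
    }
  }
  if (nrow(batch) == 0L) {
    return(data.frame(row = integer(0), certificate_id = character(0),
                      field = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }

  used <- sapply(CAUSE_COLUMNS, function(cl) trimws(batch[[cl]]) != "")
  used <- matrix(used, nrow = nrow(batch))
  for (i in seq_along(INTERVAL_COLUMNS)) {
    iv <- parse_interval(batch[[INTERVAL_COLUMNS[i]]])
    add(!iv$ok, INTERVAL_COLUMNS[i],
        "interval must be encoded 'value;unit' with a known unit")
    add(iv$present & iv$ok & !used[, i], INTERVAL_COLUMNS[i],
        "interval present on an empty cause line")
  }
  add(rowSums(used) == 0L, "part1", "no cause reported on any Part 1 line")
  add(!used[, 1L] & rowSums(used[, -1L, drop = FALSE]) > 0L, "cause1a",
      "leading blank line: Part 1 does not start at line a")
  add(batch$arm == "pre_intervention" & !is.na(batch$months_since_training),
      "months_since_training",
      "months_since_training must be absent for pre-intervention certificates")
  add(!is.na(batch$age_value) & batch$age_value < 0, "age_value",
      "age_value must be non-negative")

  if (length(findings) == 0L) {
    data.frame(row = integer(0), certificate_id = character(0),
               field = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, findings)
    out[order(out$row, out$field), , drop = FALSE]
  }
}

# Assessment IO ------------------------------------------------------------

ASSESSMENT_COLUMNS <- c("certificate_id", "arm", ERROR_TYPES, ERROR_SUBTYPES,
                        "n_major", "n_minor", "score", "correct")

#' Write an assessment table to CSV
#'
#' Combines certificates, their error profiles and scores into the assessment
#' schema: identifier, study arm, the seven error flags, the four
#' additional-error subtype flags, major/minor counts, the composite score
#' and the correctness flag. Round-trips through [read_assessment()].
#'
#' @param batch certificate batch (provides `certificate_id` and `arm`).
#' @param profiles error-profile data.frame from [assess_certificates()].
#' @param scores score data.frame from [score_profiles()].
#' @param path output path.
#' @export
write_assessment <- function(batch, profiles, scores, path) {
  if (nrow(batch) != nrow(profiles) || nrow(batch) != nrow(scores)) {
    stop("batch, profiles and scores must have one row per certificate")
  }
  out <- data.frame(certificate_id = batch$certificate_id,
                    arm = batch$arm, stringsAsFactors = FALSE)
  out <- cbind(out, profiles[c(ERROR_TYPES, ERROR_SUBTYPES)],
               scores[c("n_major", "n_minor", "score", "correct")])
  utils::write.csv(out[ASSESSMENT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read an assessment table from CSV
#'
#' @param path path written by [write_assessment()].
#' @return data.frame with the assessment schema (flags as logicals).
#' @export
read_assessment <- function(path) {
  if (!file.exists(path)) stop("assessment file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ASSESSMENT_COLUMNS, names(out))
  if (length(missing) > 0L) {
    stop("assessment CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c(ERROR_TYPES, ERROR_SUBTYPES, "correct")) {
    out[[col]] <- as.logical(out[[col]])
  }
  out$certificate_id <- as.character(out$certificate_id)
  out[ASSESSMENT_COLUMNS]
}
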