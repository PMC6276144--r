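# Error detectors ----------------------------------------------------------
#
# Deterministic, lexicon-driven implementations of the seven certification
# error types (four major, three minor) and the additional-error subtypes.
# Every detector is vectorized over a certificate batch and returns one
# logical per certificate; `assess_certificates()` runs them all.

# logical matrix n x 4: which Part 1 lines carry text
used_lines <- function(batch) {
  m <- sapply(CAUSE_COLUMNS, function(cl) trimws(as.character(batch[[cl]])) != "")
  matrix(m, nrow = nrow(batch), dimnames = list(NULL, CAUSE_COLUMNS))
}

# index (1..4) of the lowest used Part 1 line (the UCOD line); NA if none
ucod_position <- function(batch) {
  u <- used_lines(batch)
  pos <- apply(u, 1L, function(r) if (any(r)) max(which(r)) else NA_integer_)
  as.integer(pos)
}

# text of the UCOD line ("" when no line is used)
ucod_text <- function(batch) {
  pos <- ucod_position(batch)
  out <- character(nrow(batch))
  for (p in 1:4) {
    sel <- !is.na(pos) & pos == p
    out[sel] <- batch[[CAUSE_COLUMNS[p]]][sel]
  }
  out
}

#' Detect multiple causes recorded on a single line
#'
#' Only one condition should be recorded per Part 1 line; a line whose text
#' splits on any configured conjunction token (";", ",", " y ", " con ",
#' " and " by default) into two or more non-empty phrases is flagged.
#' Multiword single conditions without separators are not split.
#'
#' @param batch certificate batch data.frame.
#' @param config a [rule_config()].
#' @return logical vector, one per certificate (TRUE if any Part 1 line
#'   carries multiple causes).
#' @export
detect_multiple_causes <- function(batch, config = default_rule_config()) {
  if (nrow(batch) == 0L) return(logical(0))
  split_re <- phrase_regex(config$conjunction_tokens)
  flag_line <- function(text) {
    text <- normalize_text(text)
    parts <- strsplit(text, split_re)
    vapply(parts, function(p) sum(trimws(p) != "") >= 2L, logical(1))
  }
  out <- rep(FALSE, nrow(batch))
  for (cl in CAUSE_COLUMNS) out <- out | flag_line(batch[[cl]])
  out
}

#' Detect missing disease time intervals
#'
#' The time interval should be entered for every condition in Part 1; the
#' flag is raised when any used Part 1 line lacks a parseable interval.
#' Part 2 is not checked: Part 1 intervals are the mandatory field.
#'
#' @inheritParams detect_multiple_causes
#' @return logical vector.
#' @export
detect_missing_interval <- function(batch, config = default_rule_config()) {
  if (nrow(batch) == 0L) return(logical(0))
  u <- used_lines(batch)
  missing <- sapply(seq_along(INTERVAL_COLUMNS), function(i) {
    iv <- parse_interval(batch[[INTERVAL_COLUMNS[i]]])
    u[, i] & (!iv$present | is.na(iv$value))
  })
  rowSums(matrix(missing, nrow = nrow(batch))) > 0L
}

#' Detect a clinically improbable sequence of events
#'
#' Each used Part 1 line is mapped to a condition category via the configured
#' lexicon. The flag is raised when an adjacent used pair (the line below as
#' cause of the line above) is not in the reflexive transitive closure of the
#' configured cause-to-consequence relation, or when the underlying-cause
#' line's category is marked non-initiating. Unmapped conditions are treated
#' as compatible and never trigger the flag.
#'
#' @inheritParams detect_multiple_causes
#' @return logical vector.
#' @export
detect_incorrect_sequence <- function(batch, config = default_rule_config()) {
  n <- nrow(batch)
  if (n == 0L) return(logical(0))
  cats <- sapply(CAUSE_COLUMNS, function(cl) condition_category(batch[[cl]], config))
  cats <- matrix(cats, nrow = n)
  u <- used_lines(batch)
  out <- rep(FALSE, n)
  cl <- config$closure
  for (p in 1:3) { # adjacent pairs (p, p+1): line p+1 causes line p
    both <- u[, p] & u[, p + 1L]
    lower <- cats[, p + 1L]
    upper <- cats[, p]
    mapped <- both & !is.na(lower) & !is.na(upper)
    if (any(mapped)) {
      ok <- cl[cbind(match(lower[mapped], rownames(cl)),
                     match(upper[mapped], colnames(cl)))]
      out[which(mapped)[!ok]] <- TRUE
    }
  }
  ucat <- condition_category(ucod_text(batch), config)
  out | (!is.na(ucat) & ucat %in% config$non_initiating_categories)
}

#' Detect an ill-defined underlying cause of death
#'
#' The underlying cause is the lowest used Part 1 line; the flag is raised
#' when its normalized text is in the ill-defined lexicon (modes of dying,
#' organ failures, symptoms/signs, shock).
#'
#' @inheritParams detect_multiple_causes
#' @return logical vector.
#' @export
detect_ill_defined_ucod <- function(batch, config = default_rule_config()) {
  if (nrow(batch) == 0L) return(logical(0))
  normalize_text(ucod_text(batch)) %in% config$ill_defined_lexicon
}

#' Detect blank lines within the sequence of events
#'
#' Raised when an empty Part 1 line lies strictly between two used lines.
#' Trailing blanks are always allowed; a leading blank (an empty line "a")
#' is a structural finding reported by [validate_certificates()], not this
#' error.
#'
#' @inheritParams detect_multiple_causes
#' @return logical vector.
#' @export
detect_blank_lines <- function(batch, config = default_rule_config()) {
  if (nrow(batch) == 0L) return(logical(0))
  u <- used_lines(batch)
  before <- t(apply(u, 1L, cummax)) > 0 # a used line at or above
  after <- t(apply(u[, 4:1, drop = FALSE], 1L, cummax))[, 4:1, drop = FALSE] > 0
  gap <- !u & cbind(FALSE, before[, 1:3, drop = FALSE]) &
    cbind(after[, 2:4, drop = FALSE], FALSE)
  rowSums(gap) > 0L
}

#' Detect abbreviations in the certified causes
#'
#' Scans all cause text (Part 1 lines and Part 2). A token is an abbreviation
#' when it matches the configured abbreviation lexicon (case-insensitively)
#' or is an all-capitals token of 2 to 6 letters absent from the whitelist.
#'
#' @inheritParams detect_multiple_causes
#' @return logical vector.
#' @export
detect_abbreviations <- function(batch, config = default_rule_config()) {
  n <- nrow(batch)
  if (n == 0L) return(logical(0))
  text_cols <- c(CAUSE_COLUMNS, "part2")
  joined <- do.call(paste, c(lapply(text_cols, function(cl) {
    x <- as.character(batch[[cl]]); x[is.na(x)] <- ""; x
  }), sep = " | "))

  lex <- rep(FALSE, n)
  if (length(config$abbreviation_lexicon) > 0L) {
    pat <- paste0("(^|[^a-z0-9])(",
                  paste(config$abbreviation_lexicon, collapse = "|"),
                  ")([^a-z0-9]|$)")
    lex <- grepl(pat, tolower(chartr("áéíóúüñ",
                                     "aeiouun", joined)))
  }

  caps <- regmatches(joined, gregexpr("\\b[A-Z]{2,6}\\b", joined))
  wl <- toupper(config$abbreviation_whitelist)
  caps_hit <- vapply(caps, function(tk) any(!(tk %in% wl)), logical(1))
  lex | caps_hit
}

#' Detect additional certification errors (subtypes)
#'
#' Four under-specification subtypes, reported separately and aggregated into
#' the single minor error type "additional errors":
#' \itemize{
#'   \item \code{external_missing_details}: the underlying cause is an
#'     external cause/injury but its text carries neither an intent term nor
#'     a mechanism term.
#'   \item \code{neoplasm_missing_details}: some cause statement (a Part 1
#'     line or Part 2) mentions a neoplasm without both a behaviour qualifier
#'     (malignant/benign/...) and a site.
#'   \item \code{age_no_units}: the deceased's age has no units recorded.
#'   \item \code{other_additional}: hypertension without essential/secondary
#'     specification, diabetes without type, or a fully specified
#'     UCOD-capable condition recorded in Part 2 while Part 1's underlying
#'     cause is ill-defined.
#' }
#'
#' @inheritParams detect_multiple_causes
#' @return data.frame with the four logical subtype columns.
#' @export
detect_additional_errors <- function(batch, config = default_rule_config()) {
  n <- nrow(batch)
  if (n == 0L) {
    return(data.frame(external_missing_details = logical(0),
                      neoplasm_missing_details = logical(0),
                      age_no_units = logical(0),
                      other_additional = logical(0)))
  }
  units <- lapply(c(CAUSE_COLUMNS, "part2"),
                  function(cl) normalize_text(batch[[cl]]))
  any_unit <- function(f) Reduce(`|`, lapply(units, f))
  contains <- function(x, terms) {
    grepl(paste0("(^|[^a-z])", phrase_regex(terms), "([^a-z]|$)"), x)
  }

  ucod <- normalize_text(ucod_text(batch))
  external <- contains(ucod, config$external_cause_terms) &
    !contains(ucod, config$intent_terms) &
    !contains(ucod, config$mechanism_terms)

  neoplasm <- any_unit(function(x) {
    contains(x, config$neoplasm_terms) &
      !(contains(x, config$neoplasm_behaviour_terms) &
          contains(x, config$neoplasm_site_terms))
  })

  age <- is.na(batch$age_unit) | trimws(as.character(batch$age_unit)) == ""

  hyper <- any_unit(function(x) {
    contains(x, config$hypertension_terms) &
      !contains(x, config$hypertension_qualifiers)
  })
  diab <- any_unit(function(x) {
    contains(x, config$diabetes_terms) &
      !contains(x, config$diabetes_qualifiers)
  })
  part2 <- normalize_text(batch$part2)
  ucod_in_part2 <- contains(part2, config$ucod_capable_terms) &
    (ucod %in% config$ill_defined_lexicon)

  data.frame(external_missing_details = external,
             neoplasm_missing_details = neoplasm,
             age_no_units = age,
             other_additional = hyper | diab | ucod_in_part2)
}

#' Assess a batch of certificates against the error taxonomy
#'
#' Runs all seven detectors (plus the additional-error subtypes) and returns
#' one error profile per certificate. Certificates must be structurally valid
#' first; assessment stops with an error listing the findings otherwise.
#'
#' @param batch certificate batch data.frame (see [read_certificates()]).
#' @param config a [rule_config()]; defaults to the shipped configuration.
#' @param check logical; run [validate_certificates()] first (default TRUE).
#' @return data.frame with one row per certificate: the seven error-type
#'   flags, the four subtype flags, and `additional_errors` equal to the
#'   disjunction of the subtypes.
#' @export
assess_certificates <- function(batch, config = default_rule_config(),
                                check = TRUE) {
  if (check) {
    findings <- validate_certificates(batch)
    if (nrow(findings) > 0L) {
      stop("batch is not structurally valid; first finding: row ",
           findings$row[1L], " [", findings$field[1L], "] ",
           findings$message[1L],
           " (", nrow(findings), " finding(s) in total)")
    }
  }
  subtypes <- detect_additional_errors(batch, config)
  out <- data.frame(
    multiple_causes_per_line = detect_multiple_causes(batch, config),
    missing_time_interval = detect_missing_interval(batch, config),
    incorrect_sequence = detect_incorrect_sequence(batch, config),
    ill_defined_ucod = detect_ill_defined_ucod(batch, config),
    blank_lines = detect_blank_lines(batch, config),
    abbreviations = detect_abbreviations(batch, config),
    additional_errors = Reduce(`|`, subtypes)
  )
  cbind(out, subtypes)
}
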