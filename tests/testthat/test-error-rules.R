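# Independent phrase-count oracle: a line holds multiple causes iff
# splitting on the conjunction tokens leaves >= 2 non-empty phrases.
phrase_count <- function(text) {
  for (tok in c(";", ",", " y ", " con ", " and ")) {
    text <- gsub(tok, "", text, fixed = TRUE)
  }
  sum(trimws(strsplit(text, "")[[1]]) != "")
}

test_that("multiple causes per line are split on conjunctions only", {
  cases <- list(
    list(text = "neumonia; sepsis", expected = TRUE),
    list(text = "neumonia", expected = FALSE),
    list(text = "insuficiencia renal cronica", expected = FALSE), # multiword
    list(text = "diabetes mellitus y sepsis", expected = TRUE),
    list(text = "infarto, shock", expected = TRUE),
    list(text = "", expected = FALSE)
  )
  for (cs in cases) {
    b <- make_record(cause1a = cs$text,
                     interval1a = if (cs$text == "") "" else "1;days",
                     cause1b = "tuberculosis pulmonar", interval1b = "2;years")
    expect_identical(detect_multiple_causes(b, test_rules), cs$expected,
                     label = cs$text)
    if (cs$text != "") {
      expect_identical(cs$expected, phrase_count(normalize_text(cs$text)) >= 2,
                       label = paste("oracle:", cs$text))
    }
  }
})

test_that("a single missing Part 1 interval raises the time-interval flag", {
  three_used <- make_record(cause1a = "sepsis", interval1a = "1;days",
                            cause1b = "neumonia bacteriana", interval1b = "4;days",
                            cause1c = "enfermedad pulmonar obstructiva cronica",
                            interval1c = "")
  expect_true(detect_missing_interval(three_used, test_rules))
  all_present <- make_record(cause1a = "sepsis", interval1a = "1;days",
                             cause1b = "neumonia bacteriana", interval1b = "4;days")
  expect_false(detect_missing_interval(all_present, test_rules))
  # Part 2 carries no interval and is not checked
  with_part2 <- make_record(part2 = "diabetes mellitus tipo 2")
  expect_false(detect_missing_interval(with_part2, test_rules))
})

# Reachability oracle over the shipped relation: breadth-first search on the
# raw edge list, independent of the closure matrix the detector uses.
reachable <- function(config, from, to) {
  edges <- config$causal_relation
  if (from == to) return(TRUE)
  frontier <- from
  seen <- character(0)
  while (length(frontier) > 0L) {
    nxt <- unique(edges[edges[, 1] %in% frontier, 2])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

test_that("sequence checking accepts exactly the causal closure", {
  ok <- make_record(cause1a = "sepsis", interval1a = "1;days",
                    cause1b = "diabetes mellitus tipo 2", interval1b = "9;years")
  expect_false(detect_incorrect_sequence(ok, test_rules))

  bad <- make_record(cause1a = "diabetes mellitus tipo 2", interval1a = "9;years",
                     cause1b = "fractura de femur", interval1b = "2;days")
  expect_true(detect_incorrect_sequence(bad, test_rules))

  # the oracle agrees on both shipped pairs
  cat_of <- function(term) unname(test_rules$categories[term])
  expect_true(reachable(test_rules, cat_of("diabetes mellitus tipo 2"),
                        cat_of("sepsis")))
  expect_false(reachable(test_rules, cat_of("fractura de femur"),
                         cat_of("diabetes mellitus tipo 2")))

  single <- make_record(cause1a = "tuberculosis pulmonar")
  expect_false(detect_incorrect_sequence(single, test_rules))

  # unmapped conditions never trigger the flag
  unmapped <- make_record(cause1a = "condicion rarisima x", interval1a = "1;days",
                          cause1b = "otra condicion rara", interval1b = "2;days")
  expect_false(detect_incorrect_sequence(unmapped, test_rules))

  # a non-initiating underlying cause is an incorrect sequence by itself
  sepsis_ucod <- make_record(cause1a = "sepsis")
  expect_true(detect_incorrect_sequence(sepsis_ucod, test_rules))
})

test_that("detector flags match the reachability oracle across term pairs", {
  terms <- names(test_rules$categories)
  set.seed(31)
  for (i in 1:40) {
    pair <- sample(terms, 2L)
    b <- make_record(cause1a = pair[1], interval1a = "1;days",
                     cause1b = pair[2], interval1b = "2;years")
    compatible <- reachable(test_rules,
                            unname(test_rules$categories[pair[2]]),
                            unname(test_rules$categories[pair[1]]))
    ucod_bad <- unname(test_rules$categories[pair[2]]) %in%
      test_rules$non_initiating_categories
    expect_identical(detect_incorrect_sequence(b, test_rules),
                     !compatible || ucod_bad,
                     label = paste(pair, collapse = " <- "))
  }
})

test_that("the ill-defined lexicon is matched on the underlying cause only", {
  expect_true(detect_ill_defined_ucod(make_record(cause1a = "paro cardiaco"),
                                      test_rules))
  expect_true(detect_ill_defined_ucod(
    make_record(cause1a = "Insuficiencia Hepática"), test_rules))
  expect_false(detect_ill_defined_ucod(
    make_record(cause1a = "tuberculosis pulmonar"), test_rules))
  # an ill-defined immediate cause above a specific UCOD is fine
  b <- make_record(cause1a = "paro cardiaco", interval1a = "1;hours",
                   cause1b = "tuberculosis pulmonar", interval1b = "2;years")
  expect_false(detect_ill_defined_ucod(b, test_rules))
})

test_that("blank lines count only strictly within the chain", {
  gap <- make_record(cause1a = "sepsis", interval1a = "1;days",
                     cause1b = "", interval1b = "",
                     cause1c = "tuberculosis pulmonar", interval1c = "1;years")
  expect_true(detect_blank_lines(gap, test_rules))

  trailing <- make_record(cause1a = "sepsis", interval1a = "1;days",
                          cause1b = "tuberculosis pulmonar", interval1b = "1;years")
  expect_false(detect_blank_lines(trailing, test_rules))

  leading <- make_record(cause1a = "", interval1a = "",
                         cause1b = "sepsis", interval1b = "1;days",
                         cause1c = "tuberculosis pulmonar", interval1c = "1;years")
  expect_false(detect_blank_lines(leading, test_rules))
})

test_that("abbreviations are caught in Part 1, Part 2 and by capitalization", {
  expect_true(detect_abbreviations(make_record(cause1a = "IAM"), test_rules))
  expect_true(detect_abbreviations(make_record(part2 = "VIH"), test_rules))
  expect_true(detect_abbreviations(make_record(part2 = "tbc"), test_rules))
  # unknown all-caps token
  expect_true(detect_abbreviations(make_record(cause1a = "sindrome XYZQ"),
                                   test_rules))
  expect_false(detect_abbreviations(
    make_record(cause1a = "infarto agudo de miocardio"), test_rules))
  # whitelisted roman numerals do not fire
  expect_false(detect_abbreviations(
    make_record(cause1a = "diabetes mellitus tipo II"), test_rules))
})

test_that("additional-error subtypes fire on under-specified statements", {
  ext <- make_record(cause1a = "traumatismo")
  s <- detect_additional_errors(ext, test_rules)
  expect_true(s$external_missing_details)

  specified <- make_record(
    cause1a = "traumatismo encefalocraneano por accidente de transito")
  expect_false(detect_additional_errors(specified,
                                        test_rules)$external_missing_details)

  full_neo <- make_record(cause1a = "neoplasia maligna de estomago")
  expect_false(detect_additional_errors(full_neo,
                                        test_rules)$neoplasm_missing_details)
  bare_neo <- make_record(cause1a = "neoplasia maligna")
  expect_true(detect_additional_errors(bare_neo,
                                       test_rules)$neoplasm_missing_details)

  no_units <- make_record(age_unit = "")
  expect_true(detect_additional_errors(no_units, test_rules)$age_no_units)
  expect_false(detect_additional_errors(make_record(), test_rules)$age_no_units)

  hyper <- make_record(cause1a = "hemorragia intracerebral", interval1a = "1;days",
                       cause1b = "hipertension arterial", interval1b = "8;years")
  expect_true(detect_additional_errors(hyper, test_rules)$other_additional)
  hyper_ok <- make_record(cause1a = "hemorragia intracerebral", interval1a = "1;days",
                          cause1b = "hipertension arterial esencial",
                          interval1b = "8;years")
  expect_false(detect_additional_errors(hyper_ok, test_rules)$other_additional)

  diab <- make_record(part2 = "diabetes mellitus")
  expect_true(detect_additional_errors(diab, test_rules)$other_additional)

  # a usable underlying cause hidden in Part 2 under an ill-defined UCOD
  hidden <- make_record(cause1a = "paro cardiaco",
                        part2 = "tuberculosis pulmonar")
  expect_true(detect_additional_errors(hidden, test_rules)$other_additional)
  not_hidden <- make_record(cause1a = "cirrosis hepatica",
                            part2 = "tuberculosis pulmonar")
  expect_false(detect_additional_errors(not_hidden, test_rules)$other_additional)
})

test_that("assess runs all detectors and rejects invalid batches", {
  set.seed(71)
  clean <- render_certificates(make_profile(), make_attributes(1L))
  prof <- assess_certificates(clean, test_rules)
  expect_false(any(unlist(prof[c(ERROR_FLAG_COLS, SUBTYPE_COLS)])))

  one_flag <- render_certificates(make_profile("missing_time_interval"),
                                  make_attributes(1L))
  prof <- assess_certificates(one_flag, test_rules)
  expect_true(prof$missing_time_interval)
  expect_equal(sum(unlist(prof[ERROR_FLAG_COLS])), 1L)

  broken <- make_record(interval1a = "3;")
  expect_error(assess_certificates(broken, test_rules), "finding")
})

test_that("assessment is deterministic in the record and configuration", {
  cfg <- small_config(seed = 81L, n = c(10L, 10L, 10L))
  batch <- sample_cohort(cfg)$certificates
  expect_identical(assess_certificates(batch, test_rules),
                   assess_certificates(batch, test_rules))
})

test_that("appending an ill-defined UCOD never removes error flags", {
  set.seed(97)
  grid <- all_flag_combinations()
  # keep profiles with a free Part 1 slot: blank-line layouts already use all
  # four positions when combined with an incorrect sequence
  for (i in sample(nrow(grid), 40L)) {
    flags <- grid[i, , drop = FALSE]
    args <- names(flags)[unlist(flags)]
    if (flags$additional_errors) args <- c(args, "age_no_units")
    profile <- do.call(make_profile, as.list(args))
    batch <- render_certificates(profile, make_attributes(1L))
    used <- trimws(unlist(batch[1, c("cause1a", "cause1b", "cause1c",
                                     "cause1d")])) != ""
    if (all(used)) next
    before <- sum(unlist(assess_certificates(batch, test_rules,
                                             check = FALSE)[ERROR_FLAG_COLS]))
    slot <- max(which(used)) + 1L
    batch[[paste0("cause1", letters[slot])]] <- "paro cardiaco"
    batch[[paste0("interval1", letters[slot])]] <- "1;hours"
    after <- sum(unlist(assess_certificates(batch, test_rules,
                                            check = FALSE)[ERROR_FLAG_COLS]))
    expect_gte(after, before)
  }
})
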