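# Shared fixtures: built in code, no files on disk.

# One rule config per test run; reading the YAML is not free.
test_rules <- default_rule_config()

# A single fully valid certificate row; override any field by name.
make_record <- function(certificate_id = "C-0001",
                        cause1a = "tuberculosis pulmonar",
                        interval1a = "2;months",
                        cause1b = "", interval1b = "",
                        cause1c = "", interval1c = "",
                        cause1d = "", interval1d = "",
                        part2 = "",
                        age_value = 70, age_unit = "years",
                        sex = "male", gbd_group = "communicable",
                        arm = "online",
                        seniority_years = "11-15",
                        speciality = "general_medicine",
                        facility_level = "II",
                        months_since_training = NA_real_) {
  data.frame(certificate_id = certificate_id,
             cause1a = cause1a, interval1a = interval1a,
             cause1b = cause1b, interval1b = interval1b,
             cause1c = cause1c, interval1c = interval1c,
             cause1d = cause1d, interval1d = interval1d,
             part2 = part2,
             age_value = age_value, age_unit = age_unit,
             sex = sex, gbd_group = gbd_group, arm = arm,
             seniority_years = seniority_years, speciality = speciality,
             facility_level = facility_level,
             months_since_training = months_since_training,
             stringsAsFactors = FALSE)
}

make_batch <- function(...) do.call(rbind, list(...))

ERROR_FLAG_COLS <- c("multiple_causes_per_line", "missing_time_interval",
                     "incorrect_sequence", "ill_defined_ucod",
                     "blank_lines", "abbreviations", "additional_errors")
SUBTYPE_COLS <- c("external_missing_details", "neoplasm_missing_details",
                  "age_no_units", "other_additional")

# A planted error profile row, all flags FALSE unless named TRUE.
make_profile <- function(...) {
  flags <- stats::setNames(as.list(rep(FALSE, 11L)),
                           c(ERROR_FLAG_COLS, SUBTYPE_COLS))
  on <- c(...)
  for (nm in on) flags[[nm]] <- TRUE
  flags$additional_errors <- any(unlist(flags[SUBTYPE_COLS]))
  as.data.frame(flags)
}

# Attribute rows for render_certificates.
make_attributes <- function(n, arm = "online", age_value = 65) {
  data.frame(certificate_id = sprintf("T-%04d", seq_len(n)),
             age_value = rep_len(age_value, n),
             sex = "male", gbd_group = "communicable", arm = arm,
             seniority_years = "11-15", speciality = "general_medicine",
             facility_level = "II", months_since_training = NA_real_,
             stringsAsFactors = FALSE)
}

# A small, fast synthetic configuration for pipeline tests.
small_config <- function(seed = 101L, n = c(60L, 80L, 80L)) {
  cfg <- paper_calibrated_config(seed = seed)
  cfg$n_per_arm[] <- n
  cfg
}

# All 2^7 on/off combinations of the seven error types.
all_flag_combinations <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 7L))
  names(grid) <- ERROR_FLAG_COLS
  grid
}
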