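# Synthetic certificate cohorts -------------------------------------------
#
# Seeded generator of certificate batches with *planted* error profiles:
# attributes and error flags are drawn from configured distributions, then a
# certificate is rendered whose content manifests exactly the planted flags
# under the default rule configuration. assess(render(profile)) == profile is
# the module's central contract and is tested exhaustively.

SYN_ARM_LEVELS <- c("pre_intervention", "online", "online_training")

#' Construct a synthetic-cohort configuration
#'
#' @param n_per_arm named integer vector of cohort sizes for the
#'   pre-intervention, online, and online-and-training arms.
#' @param error_probs 7 x 3 matrix of per-arm base probabilities for each
#'   error type (rows named by error type, columns by arm).
#' @param subtype_weights 4 x 3 matrix of per-arm marginal prevalences for
#'   the additional-error subtypes; rescaled so that within each arm they
#'   sum to that arm's additional-errors probability (the study counted at
#'   most one subtype per certificate).
#' @param attributes named list of category weight vectors: `age_bands`,
#'   `sex`, `gbd_group` (the three non-ill-defined groups; the ill-defined
#'   group is determined by the planted ill-defined-UCOD flag),
#'   `seniority_years`, `speciality`, `facility_level`,
#'   `months_since_training` (bands, online-and-training arm only). Weights
#'   are normalized internally.
#' @param age_effect per-year log-odds increment applied to every error
#'   type's logit, centred at the cohort's expected age so the arm base
#'   probabilities remain marginal prevalences.
#' @param age_centre centring constant in years; `NULL` (default) derives it
#'   from the configured age distribution.
#' @param doctor_sd standard deviation of an optional shared per-doctor
#'   random intercept on every error logit (default 0 = off); available for
#'   clustering sensitivity experiments.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_arm, error_probs, subtype_weights,
                             attributes, age_effect = log(1.009),
                             age_centre = NULL, doctor_sd = 0, seed = 1L) {
  stopifnot(length(n_per_arm) == 3L, all(n_per_arm >= 1L))
  names(n_per_arm) <- SYN_ARM_LEVELS
  error_probs <- as.matrix(error_probs)
  stopifnot(identical(dim(error_probs), c(7L, 3L)))
  rownames(error_probs) <- ERROR_TYPES
  colnames(error_probs) <- SYN_ARM_LEVELS
  if (any(error_probs < 0 | error_probs > 1)) {
    stop("error probabilities must lie in [0, 1]")
  }
  subtype_weights <- as.matrix(subtype_weights)
  stopifnot(identical(dim(subtype_weights), c(4L, 3L)))
  rownames(subtype_weights) <- ERROR_SUBTYPES
  colnames(subtype_weights) <- SYN_ARM_LEVELS
  if (any(subtype_weights < 0)) stop("subtype weights must be non-negative")

  required_attr <- c("age_bands", "sex", "gbd_group", "seniority_years",
                     "speciality", "facility_level", "months_since_training")
  missing <- setdiff(required_attr, names(attributes))
  if (length(missing) > 0L) {
    stop("attribute distribution(s) missing: ", paste(missing, collapse = ", "))
  }
  for (nm in required_attr) {
    w <- attributes[[nm]]
    if (any(w < 0) || sum(w) <= 0) stop("invalid weights for ", nm)
    attributes[[nm]] <- w / sum(w)
  }
  stopifnot(identical(names(attributes$age_bands), AGE_BANDS),
            identical(names(attributes$sex), CERT_ENUMS$sex),
            identical(names(attributes$gbd_group),
                      c("communicable", "non_communicable", "external")),
            identical(names(attributes$seniority_years),
                      CERT_ENUMS$seniority_years),
            identical(names(attributes$speciality), CERT_ENUMS$speciality),
            identical(names(attributes$facility_level),
                      CERT_ENUMS$facility_level),
            identical(names(attributes$months_since_training), MONTHS_BANDS))

  if (is.null(age_centre)) {
    band_mean <- c(`0-4` = 2, `5-44` = 24.5, `45-64` = 54.5,
                   `65-74` = 69.5, `75-84` = 79.5, `>=85` = 92)
    age_centre <- sum(band_mean * attributes$age_bands)
  }

  cfg <- structure(list(
    n_per_arm = n_per_arm, error_probs = error_probs,
    subtype_weights = subtype_weights, attributes = attributes,
    age_effect = age_effect, age_centre = age_centre,
    doctor_sd = doctor_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
  # fail early if the subtype margins cannot be realised
  for (arm in SYN_ARM_LEVELS) subtype_branch_probs(cfg, arm)
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> seed", x$seed, "\n")
  cat("  n per arm:", paste(x$n_per_arm, collapse = " / "), "\n")
  cat("  age effect per year:", format(exp(x$age_effect), digits = 4),
      "(odds), centred at", round(x$age_centre, 1), "y\n")
  cat("  error probabilities (base, by arm):\n")
  print(round(x$error_probs, 3))
  invisible(x)
}

#' The calibrated default configuration
#'
#' Arm sizes of 300 / 900 / 900 certificates, per-arm error-type base
#' probabilities and additional-error subtype margins matching the published
#' per-arm prevalences of the Peruvian certification-quality study the
#' generator emulates, attribute distributions proportional to that study's
#' reported category counts, and a per-year age effect of odds 1.009 on
#' every error type. Each field carries a provenance note in the `notes`
#' attribute.
#'
#' @param seed integer seed for the cohort draw.
#' @return a [synthetic_config()].
#' @export
paper_calibrated_config <- function(seed = 1L) {
  error_probs <- matrix(c(
    0.020, 0.013, 0.006,  # multiple causes per line
    0.960, 0.471, 0.300,  # missing time interval
    0.403, 0.259, 0.179,  # incorrect sequence
    0.520, 0.454, 0.389,  # ill-defined underlying cause
    0.113, 0.002, 0.003,  # blank lines within the chain
    0.117, 0.046, 0.041,  # abbreviations
    0.323, 0.266, 0.210   # additional errors
  ), nrow = 7L, byrow = TRUE)
  subtype_weights <- matrix(c(
    0.047, 0.046, 0.021,  # external cause, missing details
    0.150, 0.081, 0.063,  # neoplasm, missing details
    0.000, 0.002, 0.006,  # no units in age
    0.127, 0.137, 0.120   # other (hypertension/diabetes unspecified, ...)
  ), nrow = 4L, byrow = TRUE)
  attributes <- list(
    age_bands = stats::setNames(c(194, 248, 373, 368, 516, 394), AGE_BANDS),
    sex = c(male = 1087, female = 1007),
    gbd_group = c(communicable = 730, non_communicable = 1175, external = 71),
    seniority_years = stats::setNames(c(141, 405, 412, 370, 245, 239, 288),
                                      CERT_ENUMS$seniority_years),
    speciality = stats::setNames(c(468, 746, 165, 178, 57, 36, 170, 63, 217),
                                 CERT_ENUMS$speciality),
    facility_level = stats::setNames(c(35, 982, 1083), CERT_ENUMS$facility_level),
    months_since_training = stats::setNames(c(234, 455, 211), MONTHS_BANDS)
  )
  cfg <- synthetic_config(
    n_per_arm = c(300L, 900L, 900L),
    error_probs = error_probs,
    subtype_weights = subtype_weights,
    attributes = attributes,
    age_effect = log(1.009),
    seed = seed
  )
  attr(cfg, "notes") <- c(
    n_per_arm = "study arm sizes: 300 pre-intervention, 900 online, 900 online+training",
    error_probs = "per-arm base probabilities set to the published per-arm error prevalences",
    subtype_weights = "additional-error subtype margins set to the published subtype prevalences",
    attributes = "category weights proportional to the published certificate counts per attribute",
    age_effect = "per-year odds increment 1.009 from the published ordinal regression"
  )
  cfg
}

# Conditional subtype draw probabilities. The external-cause subtype cannot
# be rendered together with an ill-defined UCOD (both constrain the lowest
# Part 1 line), so its mass is concentrated on the non-ill-defined stratum
# and the other subtypes are reweighted per stratum so that all four
# marginal subtype prevalences match the configured targets exactly.
subtype_branch_probs <- function(config, arm) {
  p_add <- config$error_probs["additional_errors", arm]
  p_ill <- config$error_probs["ill_defined_ucod", arm]
  t0 <- config$subtype_weights[, arm]
  if (p_add == 0 || sum(t0) == 0) {
    zero <- stats::setNames(rep(0, 4L), ERROR_SUBTYPES)
    return(list(not_ill = zero, ill = zero))
  }
  t <- p_add * t0 / sum(t0) # marginal subtype prevalences
  ext <- "external_missing_details"
  others <- setdiff(ERROR_SUBTYPES, ext)
  q_ext <- if (p_ill < 1) t[ext] / (p_add * (1 - p_ill)) else Inf
  if (q_ext > 1 + 1e-12) {
    stop("external-cause subtype margin (", signif(t[ext], 3),
         ") is unattainable given the ill-defined UCOD prevalence ", p_ill)
  }
  q_ext <- min(q_ext, 1)
  q_not <- stats::setNames(rep(0, 4L), ERROR_SUBTYPES)
  q_not[ext] <- q_ext
  if (sum(t[others]) > 0) {
    q_not[others] <- (1 - q_ext) * t[others] / sum(t[others])
  }
  q_ill <- stats::setNames(rep(0, 4L), ERROR_SUBTYPES)
  if (p_ill > 0) {
    q_ill[others] <- (t[others] / p_add - (1 - p_ill) * q_not[others]) / p_ill
    if (any(q_ill < -1e-12)) stop("subtype margins are infeasible")
    q_ill <- pmax(q_ill, 0)
    if (sum(q_ill) > 0) q_ill <- q_ill / sum(q_ill)
  }
  list(not_ill = q_not, ill = q_ill)
}

# Rendering vocabulary (consistent with the shipped default rule config) ----

RENDER_TEMPLATES <- data.frame(
  lower = c("enfermedad pulmonar obstructiva cronica",
            "diabetes mellitus tipo 2",
            "hipertension arterial esencial",
            "tuberculosis pulmonar",
            "neoplasia maligna de estomago",
            "cirrosis hepatica"),
  upper = c("neumonia bacteriana",
            "insuficiencia renal cronica",
            "hemorragia intracerebral",
            "neumonia bacteriana",
            "sepsis",
            "sepsis"),
  two_line = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

RENDER_ILL_TERMS <- c("paro cardiaco", "paro respiratorio",
                      "paro cardiorrespiratorio", "insuficiencia cardiaca",
                      "insuficiencia hepatica", "insuficiencia respiratoria",
                      "falla organica multiple", "shock", "senilidad")
RENDER_EXTERNAL_TERMS <- c("traumatismo", "politraumatismo")
RENDER_MC_LINE <- "neumonia bacteriana y sepsis"
RENDER_FILLER <- "cirrosis hepatica"
RENDER_SEQ_UPPER <- "fractura de femur"          # no category causes injury
RENDER_SEQ_UPPER_FOR_INJURY <- "diabetes mellitus tipo 2"
RENDER_OTHER_ITEMS <- c("hipertension arterial", "diabetes mellitus")
RENDER_ABBREVIATIONS <- c("TBC", "IAM", "EPOC", "HTA", "ACV")
RENDER_INTERVAL_UNITS <- c("hours", "days", "weeks", "months", "years")

#' Render certificates that manifest planted error profiles
#'
#' Builds Part 1 / Part 2 content from the shipped lexicons so that, under
#' the default rule configuration, every planted flag is detected and every
#' unplanted flag is guaranteed absent. Uses the current RNG stream for
#' cosmetic choices (which template, interval values), so wrap in
#' `set.seed()` for reproducibility. One profile combination is impossible
#' by construction - an external-cause subtype together with an ill-defined
#' underlying cause, since both constrain the same line - and raises an
#' error rather than silently dropping a flag.
#'
#' @param profiles data.frame of planted flags: the seven error types plus
#'   the four subtype columns (as from [assess_certificates()]).
#' @param attributes data.frame, row-aligned with `profiles`, with columns
#'   `certificate_id`, `age_value`, `sex`, `gbd_group`, `arm`,
#'   `seniority_years`, `speciality`, `facility_level`,
#'   `months_since_training`.
#' @return a certificate batch data.frame.
#' @export
render_certificates <- function(profiles, attributes) {
  n <- nrow(profiles)
  stopifnot(nrow(attributes) == n)
  need <- c(ERROR_TYPES, ERROR_SUBTYPES)
  missing <- setdiff(need, names(profiles))
  if (length(missing) > 0L) {
    stop("profiles are missing column(s): ", paste(missing, collapse = ", "))
  }
  sub_any <- Reduce(`|`, profiles[ERROR_SUBTYPES])
  if (any(profiles$additional_errors != sub_any)) {
    stop("additional_errors must equal the disjunction of the subtype flags")
  }
  bad <- profiles$ill_defined_ucod & profiles$external_missing_details
  if (any(bad)) {
    stop("cannot render an external-cause subtype together with an ",
         "ill-defined underlying cause (row ", which(bad)[1L], ")")
  }

  MC <- profiles$multiple_causes_per_line
  MTI <- profiles$missing_time_interval
  SEQ <- profiles$incorrect_sequence
  ILL <- profiles$ill_defined_ucod
  BL <- profiles$blank_lines
  ABBR <- profiles$abbreviations
  EXT <- profiles$external_missing_details
  NEO <- profiles$neoplasm_missing_details
  AGEU <- profiles$age_no_units
  OTH <- profiles$other_additional

  tidx <- sample.int(nrow(RENDER_TEMPLATES), n, replace = TRUE)
  ucod <- RENDER_TEMPLATES$lower[tidx]
  ucod[ILL] <- sample(RENDER_ILL_TERMS, sum(ILL), replace = TRUE)
  ucod[EXT] <- sample(RENDER_EXTERNAL_TERMS, sum(EXT), replace = TRUE)
  ucod_is_injury <- EXT # the only rendered injury UCODs

  compat_upper <- RENDER_TEMPLATES$upper[tidx]
  compat_upper[ILL] <- sample(RENDER_ILL_TERMS, sum(ILL), replace = TRUE)
  compat_upper[EXT] <- "sepsis" # trauma leading to sepsis
  incompat_upper <- ifelse(ucod_is_injury, RENDER_SEQ_UPPER_FOR_INJURY,
                           RENDER_SEQ_UPPER)
  two_line <- RENDER_TEMPLATES$two_line[tidx]
  two_line[ILL | EXT] <- stats::runif(sum(ILL | EXT)) < 0.5
  top <- ifelse(MC, RENDER_MC_LINE, RENDER_FILLER)

  L <- matrix("", n, 4L)
  sel <- BL & SEQ
  L[sel, 1L] <- top[sel]; L[sel, 3L] <- incompat_upper[sel]
  L[sel, 4L] <- ucod[sel]
  sel <- BL & !SEQ
  L[sel, 1L] <- top[sel]; L[sel, 3L] <- ucod[sel]
  sel <- !BL & SEQ & MC
  L[sel, 1L] <- RENDER_MC_LINE; L[sel, 2L] <- incompat_upper[sel]
  L[sel, 3L] <- ucod[sel]
  sel <- !BL & SEQ & !MC
  L[sel, 1L] <- incompat_upper[sel]; L[sel, 2L] <- ucod[sel]
  sel <- !BL & !SEQ & MC
  L[sel, 1L] <- RENDER_MC_LINE; L[sel, 2L] <- ucod[sel]
  sel <- !BL & !SEQ & !MC & two_line
  L[sel, 1L] <- compat_upper[sel]; L[sel, 2L] <- ucod[sel]
  sel <- !BL & !SEQ & !MC & !two_line
  L[sel, 1L] <- ucod[sel]

  used <- L != ""
  iv <- matrix("", n, 4L)
  n_used <- sum(used)
  iv[used] <- paste0(sample(1:30, n_used, replace = TRUE), ";",
                     sample(RENDER_INTERVAL_UNITS, n_used, replace = TRUE))
  # missing interval: always drop the UCOD line's interval, others at random
  ucod_pos <- apply(used, 1L, function(r) max(which(r)))
  drop_extra <- matrix(stats::runif(n * 4L) < 0.5, n, 4L)
  for (p in 1:4) {
    kill <- MTI & used[, p] & (ucod_pos == p | drop_extra[, p])
    iv[kill, p] <- ""
  }

  part2_items <- mapply(function(neo, oth, abbr, oth_item, abbr_item) {
    items <- character(0)
    if (neo) items <- c(items, "neoplasia maligna")
    if (oth) items <- c(items, oth_item)
    if (abbr) items <- c(items, abbr_item)
    paste(items, collapse = "; ")
  }, NEO, OTH, ABBR,
  sample(RENDER_OTHER_ITEMS, n, replace = TRUE),
  sample(RENDER_ABBREVIATIONS, n, replace = TRUE))

  batch <- data.frame(
    certificate_id = as.character(attributes$certificate_id),
    cause1a = L[, 1L], interval1a = iv[, 1L],
    cause1b = L[, 2L], interval1b = iv[, 2L],
    cause1c = L[, 3L], interval1c = iv[, 3L],
    cause1d = L[, 4L], interval1d = iv[, 4L],
    part2 = part2_items,
    age_value = attributes$age_value,
    age_unit = ifelse(AGEU, "", "years"),
    sex = attributes$sex,
    gbd_group = attributes$gbd_group,
    arm = attributes$arm,
    seniority_years = attributes$seniority_years,
    speciality = attributes$speciality,
    facility_level = attributes$facility_level,
    months_since_training = attributes$months_since_training,
    stringsAsFactors = FALSE
  )
  batch
}

#' Sample a synthetic certificate cohort
#'
#' Draws certifier/deceased attributes and planted error profiles per the
#' configuration, then renders certificates whose content manifests exactly
#' the planted profiles. Error flags are drawn independently given age (the
#' per-year log-odds increment applies to every type, centred so arm base
#' probabilities stay marginal). The GBD cause group is `ill_defined` if and
#' only if the planted ill-defined-UCOD flag is set, which makes the
#' "ill-defined causes have 100% any-error" property hold by construction.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `certificates` (batch data.frame) and
#'   `profiles` (planted error-profile data.frame, row-aligned).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  arm_prefix <- c(pre_intervention = "PRE", online = "ONL",
                  online_training = "ONT")
  band_lo <- c(0, 5, 45, 65, 75, 85)
  band_hi <- c(4, 44, 64, 74, 84, 99)
  months_pool <- list(`<3` = seq(0.5, 2.5, by = 0.5),
                      `3-6` = seq(3, 6, by = 0.5),
                      `>6` = seq(6.5, 12, by = 0.5))

  all_batches <- list(); all_profiles <- list()
  for (arm in SYN_ARM_LEVELS) {
    n <- config$n_per_arm[[arm]]
    at <- config$attributes
    band <- sample.int(length(AGE_BANDS), n, replace = TRUE,
                       prob = at$age_bands)
    age <- band_lo[band] +
      floor(stats::runif(n) * (band_hi[band] - band_lo[band] + 1L))
    attributes <- data.frame(
      certificate_id = sprintf("%s-%05d", arm_prefix[[arm]], seq_len(n)),
      age_value = age,
      sex = sample(names(at$sex), n, replace = TRUE, prob = at$sex),
      gbd_group = NA_character_,
      arm = arm,
      seniority_years = sample(names(at$seniority_years), n, replace = TRUE,
                               prob = at$seniority_years),
      speciality = sample(names(at$speciality), n, replace = TRUE,
                          prob = at$speciality),
      facility_level = sample(names(at$facility_level), n, replace = TRUE,
                              prob = at$facility_level),
      months_since_training = NA_real_,
      stringsAsFactors = FALSE
    )
    if (arm == "online_training") {
      mb <- sample(MONTHS_BANDS, n, replace = TRUE,
                   prob = at$months_since_training)
      attributes$months_since_training <- vapply(mb, function(b) {
        pool <- months_pool[[b]]
        pool[sample.int(length(pool), 1L)]
      }, numeric(1))
    }

    shift <- config$age_effect * (age - config$age_centre)
    if (config$doctor_sd > 0) {
      n_doc <- max(1L, ceiling(n * 0.6))
      doc_eff <- stats::rnorm(n_doc, 0, config$doctor_sd)
      shift <- shift + doc_eff[sample.int(n_doc, n, replace = TRUE)]
    }
    flags <- sapply(ERROR_TYPES, function(tp) {
      base <- config$error_probs[tp, arm]
      p <- stats::plogis(stats::qlogis(base) + shift)
      p[base == 0] <- 0; p[base == 1] <- 1
      stats::runif(n) < p
    })
    flags <- matrix(flags, nrow = n, dimnames = list(NULL, ERROR_TYPES))

    profiles <- as.data.frame(flags)
    sub <- matrix(FALSE, n, 4L, dimnames = list(NULL, ERROR_SUBTYPES))
    qq <- subtype_branch_probs(config, arm)
    add_idx <- which(profiles$additional_errors)
    for (i in add_idx) {
      q <- if (profiles$ill_defined_ucod[i]) qq$ill else qq$not_ill
      if (sum(q) == 0) q <- c(0, 0, 1, 0) # degenerate config: fall back
      sub[i, sample.int(4L, 1L, prob = q)] <- TRUE
    }
    profiles <- cbind(profiles, as.data.frame(sub))
    profiles$additional_errors <- as.logical(rowSums(sub) > 0)

    attributes$gbd_group <- ifelse(
      profiles$ill_defined_ucod, "ill_defined",
      sample(names(at$gbd_group), n, replace = TRUE, prob = at$gbd_group))

    all_batches[[arm]] <- render_certificates(profiles, attributes)
    all_profiles[[arm]] <- profiles
  }
  certificates <- do.call(rbind, all_batches)
  profiles <- do.call(rbind, all_profiles)
  rownames(certificates) <- rownames(profiles) <- NULL
  list(certificates = certificates, profiles = profiles)
}

#' Read/write synthetic configurations as YAML
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @return `read_synthetic_config` returns a [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- list(
    n_per_arm = as.list(config$n_per_arm),
    error_probs = stats::setNames(
      lapply(ERROR_TYPES, function(tp) as.list(config$error_probs[tp, ])),
      ERROR_TYPES),
    subtype_weights = stats::setNames(
      lapply(ERROR_SUBTYPES, function(s) as.list(config$subtype_weights[s, ])),
      ERROR_SUBTYPES),
    attributes = lapply(config$attributes, as.list),
    age_effect = config$age_effect,
    age_centre = config$age_centre,
    doctor_sd = config$doctor_sd,
    seed = config$seed
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) stop("synthetic configuration not found: ", path)
  raw <- yaml::read_yaml(path)
  to_mat <- function(x, rows, cols) {
    m <- t(vapply(rows, function(r) unlist(x[[r]])[cols], numeric(length(cols))))
    dimnames(m) <- list(rows, cols)
    m
  }
  synthetic_config(
    n_per_arm = unlist(raw$n_per_arm)[SYN_ARM_LEVELS],
    error_probs = to_mat(raw$error_probs, ERROR_TYPES, SYN_ARM_LEVELS),
    subtype_weights = to_mat(raw$subtype_weights, ERROR_SUBTYPES,
                             SYN_ARM_LEVELS),
    attributes = lapply(raw$attributes, unlist),
    age_effect = raw$age_effect,
    age_centre = raw$age_centre,
    doctor_sd = raw$doctor_sd %||% 0,
    seed = raw$seed
  )
}
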